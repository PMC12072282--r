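test_that("run_fold_selections yields one output per fold and method", {
  set.seed(20)
  g <- generate_continuous(continuous_spec(50, 40, 3), seed = 20)
  plan <- make_fold_plan(g$dataset$labels, 5, 0)
  sel <- run_fold_selections(g$dataset, plan,
                             selector_config(lasso_alpha = 0.05, mrmr_k = 5))
  expect_length(sel, 10)
  expect_equal(sum(sapply(sel, `[[`, "method") == "lasso"), 5)
  expect_equal(sum(sapply(sel, `[[`, "method") == "mrmr"), 5)
  expect_setequal(sapply(sel, `[[`, "fold_index"), 0:4)
})

test_that("planted features appear in most lasso fold selections", {
  g <- generate_continuous(continuous_spec(100, 500, 10), seed = 0)
  plan <- make_fold_plan(g$dataset$labels, 5, 0)
  sel <- run_fold_selections(g$dataset, plan,
                             selector_config(lasso_alpha = 0.01))
  lasso_sel <- Filter(function(s) s$method == "lasso", sel)
  appearances <- sapply(g$informative, function(f)
    sum(sapply(lasso_sel, function(s) f %in% s$feature_names)))
  expect_true(all(appearances >= 4))
})

test_that("pure-noise features rarely survive all ten fold selections", {
  # folds share 80% of samples, so an extreme noise feature can be
  # re-selected stably; the Monte-Carlo failure probability must stay small
  hits <- 0L
  for (rep in 1:20) {
    g <- generate_continuous(continuous_spec(60, 100, 0, effect_size = 0),
                             seed = 100 + rep)
    plan <- make_fold_plan(g$dataset$labels, 5, rep)
    sel <- run_fold_selections(
      g$dataset, plan, selector_config(lasso_alpha = 0.1, mrmr_k = 3))
    wt <- accumulate_weights(sel, rank_assignment(2L, 1L))
    if (length(wt$weights) && max(wt$weights) == 15) hits <- hits + 1L
  }
  expect_lte(hits, 3L)
})

test_that("weight accumulation reproduces the hand-worked two-fold example", {
  sels <- list(make_selection("lasso", 0, c("A", "B")),
               make_selection("lasso", 1, "A"),
               make_selection("mrmr", 0, c("B", "C")),
               make_selection("mrmr", 1, c("A", "C")))
  w21 <- accumulate_weights(sels, rank_assignment(2L, 1L))$weights
  expect_equal(w21[c("A", "B", "C")], c(A = 5, B = 3, C = 2))
  w12 <- accumulate_weights(sels, rank_assignment(1L, 2L))$weights
  expect_equal(w12[c("A", "B", "C")], c(A = 4, B = 3, C = 4))
  expect_equal(naive_accumulate(sels, 2, 1)[c("A", "B", "C")],
               c(A = 5, B = 3, C = 2))
})

test_that("empty selections give an empty weight table; duplicates error", {
  empty <- list(make_selection("lasso", 0, character(0)),
                make_selection("mrmr", 0, character(0)))
  expect_length(accumulate_weights(empty, rank_assignment(2L, 1L))$weights, 0)
  dup <- list(make_selection("lasso", 0, "A"),
              make_selection("lasso", 0, "B"),
              make_selection("mrmr", 0, "A"))
  expect_error(accumulate_weights(dup, rank_assignment(2L, 1L)),
               "duplicate \\(fold, method\\)")
})

test_that("accumulation matches the naive oracle and the swap identity", {
  set.seed(30)
  pool <- paste0("P", 1:20)
  for (rep in 1:30) {
    sels <- random_selections(sample(2:5, 1), pool)
    w21 <- accumulate_weights(sels, rank_assignment(2L, 1L))$weights
    w12 <- accumulate_weights(sels, rank_assignment(1L, 2L))$weights
    expected <- naive_accumulate(sels, 2, 1)
    expect_equal(w21[order(names(w21))], expected[order(names(expected))])
    # swapping the assignment swaps contributions: w21 + w12 == 3 * count
    counts <- naive_accumulate(sels, 1, 1)
    feats <- names(counts)
    expect_equal(unname(w21[feats] + w12[feats]), unname(3 * counts))
    n_folds <- length(unique(sapply(sels, `[[`, "fold_index")))
    if (length(w21)) expect_lte(max(w21), 3 * n_folds)
  }
})

test_that("threshold sweep enumerates panels for the A/B/C weight table", {
  wt <- accumulate_weights(
    list(make_selection("lasso", 0, c("A", "B")),
         make_selection("lasso", 1, "A"),
         make_selection("mrmr", 0, c("B", "C")),
         make_selection("mrmr", 1, c("A", "C"))),
    rank_assignment(2L, 1L))  # A=5, B=3, C=2
  sw <- threshold_sweep(wt)
  expect_equal(sw$k, 1:5)
  expect_equal(sw$n_features, c(3L, 3L, 2L, 1L, 1L))
  expect_equal(sw$feature_set[[1]], c("A", "B", "C"))
  expect_equal(sw$feature_set[[3]], c("A", "B"))
  expect_equal(sw$feature_set[[5]], "A")
})

test_that("degenerate sweeps behave: constant weights and singletons", {
  wt_all3 <- accumulate_weights(
    list(make_selection("lasso", 0, c("A", "B")),
         make_selection("mrmr", 0, c("A", "B"))),
    rank_assignment(2L, 1L))  # both weight 3
  sw <- threshold_sweep(wt_all3)
  expect_equal(sw$n_features, rep(2L, 3))
  expect_true(all(sapply(sw$feature_set, identical, c("A", "B"))))

  wt_one <- accumulate_weights(
    list(make_selection("mrmr", 0, "A"),
         make_selection("lasso", 0, character(0))),
    rank_assignment(2L, 1L))
  sw1 <- threshold_sweep(wt_one)
  expect_equal(nrow(sw1), 1L)
  expect_equal(sw1$feature_set[[1]], "A")
})

test_that("sweep panels are nested with non-increasing sizes", {
  set.seed(31)
  pool <- paste0("Q", 1:30)
  for (rep in 1:40) {
    n_folds <- sample(2:6, 1)
    sels <- random_selections(n_folds, pool)
    wt <- accumulate_weights(sels, rank_assignment(2L, 1L))
    if (length(wt$weights) == 0) next
    sw <- threshold_sweep(wt)
    expect_lte(max(wt$weights), 3 * n_folds)
    for (i in seq_len(nrow(sw) - 1)) {
      expect_true(all(sw$feature_set[[i + 1]] %in% sw$feature_set[[i]]))
      expect_lte(sw$n_features[i + 1], sw$n_features[i])
    }
  }
})

test_that("dynamic ranking rewards the selector with the better fold accuracy", {
  ds <- perfect_feature_dataset(n = 60, p = 6)
  plan <- make_fold_plan(ds$labels, 3, 0)
  sels <- list()
  for (fold in 0:2) {
    sels[[length(sels) + 1L]] <- make_selection("lasso", fold, "F1")  # signal
    sels[[length(sels) + 1L]] <- make_selection("mrmr", fold, "F3")   # noise
  }
  ra <- dynamic_rank_per_fold(ds, plan, sels)
  expect_true(all(sapply(ra, function(a) a$w_lasso == 2L)))

  # empty mrmr selection: lasso=2 by rule, with a log entry
  sels[[2]] <- make_selection("mrmr", 0, character(0))
  ra2 <- dynamic_rank_per_fold(ds, plan, sels)
  expect_equal(ra2[[1]]$w_lasso, 2L)
  expect_match(attr(ra2, "tie_log")[1], "empty mrmr")

  # identical selections tie, resolved to lasso=2 and logged
  sels_tie <- list()
  for (fold in 0:2) {
    sels_tie[[length(sels_tie) + 1L]] <- make_selection("lasso", fold, "F1")
    sels_tie[[length(sels_tie) + 1L]] <- make_selection("mrmr", fold, "F1")
  }
  ra3 <- dynamic_rank_per_fold(ds, plan, sels_tie)
  expect_true(all(sapply(ra3, function(a) a$w_lasso == 2L)))
  expect_match(attr(ra3, "tie_log")[1], "tie")
})
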