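test_that("clustergram z-scores rows and merges duplicates at height zero", {
  set.seed(40)
  n <- 30
  y <- rep(c(0L, 1L), each = 15)
  base <- rnorm(n)
  X <- cbind(A = base, B = base + 10,       # identical profile, shifted
             C = rnorm(n), D = -2 * base)   # D is the negated profile of A
  ds <- omics_dataset(X, y)
  cg <- clustergram(ds, c("A", "B", "C", "D"))
  expect_equal(unname(rowMeans(cg$z_matrix)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(cg$z_matrix, 1, sd)), rep(1, 4), tolerance = 1e-9)
  hc <- cg$feature_linkage
  # A and B (identical after z-scoring) merge first at height 0
  first <- hc$merge[1, ]
  expect_setequal(-first, match(c("A", "B"), cg$feature_names))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  # A vs D: correlation -1, distance 2
  D <- 1 - cor(t(cg$z_matrix))
  expect_equal(D[match("A", cg$feature_names), match("D", cg$feature_names)],
               2, tolerance = 1e-12)
})

test_that("tight correlated pairs cluster before the pairs join", {
  set.seed(41)
  n <- 50
  u <- rnorm(n); v <- rnorm(n)
  X <- cbind(P1 = u, P2 = u + rnorm(n, sd = 0.05),
             Q1 = v, Q2 = v + rnorm(n, sd = 0.05))
  ds <- omics_dataset(X, rep(c(0L, 1L), 25))
  cg <- clustergram(ds, colnames(X))
  merges <- cg$feature_linkage$merge
  first_two <- list(sort(-merges[1, ]), sort(-merges[2, ]))
  pairs <- list(sort(match(c("P1", "P2"), cg$feature_names)),
                sort(match(c("Q1", "Q2"), cg$feature_names)))
  expect_setequal(first_two, pairs)
})

test_that("clustergram is invariant to panel order and flags constants", {
  set.seed(42)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, paste0("F", 1:6)))
  ds <- omics_dataset(X, rep(c(0L, 1L), 10))
  a <- clustergram(ds, paste0("F", 1:6))
  b <- clustergram(ds, paste0("F", c(4, 2, 6, 1, 3, 5)))
  expect_identical(a$feature_order, b$feature_order)
  expect_identical(a$feature_names, b$feature_names)

  Xc <- cbind(X[, 1:3], K = rep(1, 20))
  dsc <- omics_dataset(Xc, rep(c(0L, 1L), 10))
  expect_warning(cgc <- clustergram(dsc, colnames(Xc)), "constant")
  expect_true(all(cgc$z_matrix["K", ] == 0))

  # samples grouped by class, within-class order preserved
  expect_identical(cgc$sample_order,
                   c(which(dsc$labels == 0L), which(dsc$labels == 1L)))
  expect_error(clustergram(ds, "F1"), "at least two")
})

test_that("rank bar ranks panel features by accumulated weight, ties by name", {
  set.seed(43)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  ds <- omics_dataset(X, rep(c(0L, 1L), 10))
  cg <- clustergram(ds, c("A", "B", "C"), weights = c(A = 5, B = 7, C = 5))
  expect_equal(cg$rank_bar, c(A = 2L, B = 1L, C = 3L))
})

test_that("sweep TSV round-trips at the printed precision", {
  g <- generate_continuous(continuous_spec(40, 20, 2), seed = 14)
  plan <- make_fold_plan(g$dataset$labels, 4, 0)
  sel <- run_fold_selections(g$dataset, plan,
                             selector_config(lasso_alpha = 0.05, mrmr_k = 3))
  sweeps <- list(lasso2_mrmr1 = threshold_sweep(
    accumulate_weights(sel, rank_assignment(2L, 1L))))
  rep_ <- full_sweep_evaluation(g$dataset, plan, sweeps,
                                models = c("LR", "KNN"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(rep_, f)
  back <- read_sweep_tsv(f)
  expect_equal(back$assignment, rep_$assignment)
  expect_equal(back$k, rep_$k)
  expect_equal(back$n_features, rep_$n_features)
  expect_equal(back$LR, round(rep_$LR, 5), tolerance = 1e-9)
  expect_equal(back$KNN, round(rep_$KNN, 5), tolerance = 1e-9)
})

test_that("weight-table TSV reports per-method counts and both weights", {
  sels <- list(make_selection("lasso", 0, c("A", "B")),
               make_selection("lasso", 1, "A"),
               make_selection("mrmr", 0, c("B", "C")),
               make_selection("mrmr", 1, c("A", "C")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table_tsv(sels, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$feature_name, c("A", "B", "C"))
  expect_equal(tab$selection_count_lasso, c(2L, 1L, 0L))
  expect_equal(tab$selection_count_mrmr, c(1L, 1L, 2L))
  expect_equal(tab$weight_21, c(5L, 3L, 2L))
  expect_equal(tab$weight_12, c(4L, 3L, 4L))
})

test_that("the run manifest records the penalty override and random state", {
  f <- withr::local_tempfile(fileext = ".json")
  write_run_manifest(f, selector_config(lasso_alpha = 0.01),
                     preprocess_spec(), seed = 0, random_state = 0,
                     label_mapping = c(female = 0L, male = 1L),
                     extra = list(pooled_accuracy = 0.93))
  m <- jsonlite::read_json(f)
  expect_equal(m$selector_config$lasso_alpha, 0.01)
  expect_equal(m$random_state, 0)
  expect_equal(m$seed, 0)
  expect_equal(m$label_mapping$female, 0)
  expect_equal(m$pooled_accuracy, 0.93)
})

test_that("best-result JSON carries the panel and accuracy scales", {
  best <- structure(list(assignment = "lasso2_mrmr1", k = 7L, model = "SVM",
                         feature_names = c("X1", "X2"), mean_accuracy = 1,
                         n_features = 2L, tie_break_log = character(0)),
                    class = "best_result")
  f <- withr::local_tempfile(fileext = ".json")
  write_best_json(best, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$mean_accuracy_pct, 100)
  expect_equal(unlist(j$feature_names), c("X1", "X2"))
  expect_equal(j$k, 7)
})
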