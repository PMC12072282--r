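#' Rank assignment for the two base selectors
#'
#' One selector receives weight 2 (the higher rank), the other weight 1.
#'
#' @param w_lasso,w_mrmr Integer weights; together they must be {1, 2}.
#' @return A `rank_assignment` list.
#' @export
rank_assignment <- function(w_lasso, w_mrmr) {
  w_lasso <- as.integer(w_lasso); w_mrmr <- as.integer(w_mrmr)
  if (!setequal(c(w_lasso, w_mrmr), c(1L, 2L)))
    stop("rank weights must be {1, 2} split across the two selectors")
  structure(list(w_lasso = w_lasso, w_mrmr = w_mrmr),
            class = "rank_assignment")
}

assignment_label <- function(a) sprintf("lasso%d_mrmr%d", a$w_lasso, a$w_mrmr)

#' Run both selectors on every training fold
#'
#' For each fold of the plan, fits the preprocessing on that fold's training
#' split (z-scoring for continuous data when `prep$standardize`), then runs
#' [lasso_select()] on the (standardized) training split and [mrmr_select()]
#' on the raw training split. The held-out split never enters selection.
#'
#' @param ds An [omics_dataset()].
#' @param plan A [make_fold_plan()] plan for `ds$labels`.
#' @param cfg A [selector_config()].
#' @param prep A [preprocess_spec()].
#' @return List of `2 * n_folds` `selector_output` objects (lasso then mrmr
#'   for folds 0, 1, ...).
#' @export
run_fold_selections <- function(ds, plan, cfg = selector_config(),
                                prep = preprocess_spec()) {
  stopifnot(inherits(ds, "omics_dataset"), inherits(plan, "fold_plan"))
  if (length(plan$assignments) != nrow(ds$values))
    stop("fold plan covers ", length(plan$assignments),
         " samples but dataset has ", nrow(ds$values))
  out <- vector("list", 2L * plan$n_folds)
  for (fold in seq_len(plan$n_folds) - 1L) {
    tr <- train_indices(plan, fold)
    Xtr <- ds$values[tr, , drop = FALSE]
    ytr <- ds$labels[tr]
    Xl <- Xtr
    if (ds$value_kind == "continuous" && isTRUE(prep$standardize))
      Xl <- standardize_apply(Xtr, standardize_fit(Xtr))
    las <- tryCatch(
      lasso_select(Xl, ytr, cfg, fold_index = fold),
      error = function(e) stop("fold ", fold, " (lasso): ",
                               conditionMessage(e), call. = FALSE))
    mrm <- tryCatch(
      mrmr_select(Xtr, ytr, cfg$mrmr_k, cfg, fold_index = fold),
      error = function(e) stop("fold ", fold, " (mrmr): ",
                               conditionMessage(e), call. = FALSE))
    out[[2L * fold + 1L]] <- las
    out[[2L * fold + 2L]] <- mrm
  }
  out
}

#' Accumulate rank weights over folds and selectors
#'
#' Each feature's weight is the sum, over all folds, of `w_lasso` when the
#' fold's LASSO selection contains it plus `w_mrmr` when the fold's mRMR
#' selection contains it. Features never selected are absent (implicit
#' weight 0). Features are keyed by name so column order never matters.
#'
#' @param selections List of `selector_output` objects covering every
#'   (fold, method) pair exactly once.
#' @param assignment A [rank_assignment()], or a list of per-fold
#'   assignments (dynamic mode) named/ordered by fold index.
#' @return A `feature_weight_table`: list with `weights` (named integer
#'   vector, decreasing, ties by name), `assignment`, `n_folds`, and
#'   per-method selection counts.
#' @export
accumulate_weights <- function(selections, assignment) {
  keys <- vapply(selections, function(s) paste(s$method, s$fold_index),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (fold, method) pair: ", keys[duplicated(keys)][1])
  folds <- sort(unique(vapply(selections, `[[`, integer(1), "fold_index")))
  n_folds <- length(folds)
  per_fold <- inherits(assignment, "rank_assignment") == FALSE
  if (per_fold && length(assignment) != n_folds)
    stop("per-fold assignment list must have one entry per fold")
  w <- numeric(0)
  cnt_lasso <- numeric(0)
  cnt_mrmr <- numeric(0)
  add <- function(tab, feats, inc) {
    if (length(feats) == 0L) return(tab)
    miss <- setdiff(feats, names(tab))
    if (length(miss)) tab[miss] <- 0
    tab[feats] <- tab[feats] + inc
    tab
  }
  for (s in selections) {
    a <- if (per_fold) assignment[[match(s$fold_index, folds)]] else assignment
    inc <- if (s$method == "lasso") a$w_lasso else a$w_mrmr
    w <- add(w, s$feature_names, inc)
    if (s$method == "lasso") cnt_lasso <- add(cnt_lasso, s$feature_names, 1)
    else cnt_mrmr <- add(cnt_mrmr, s$feature_names, 1)
  }
  ord <- if (length(w)) order(-w, names(w)) else integer(0)
  structure(list(weights = round(w[ord]),
                 assignment = assignment, n_folds = n_folds,
                 count_lasso = cnt_lasso, count_mrmr = cnt_mrmr),
            class = "feature_weight_table")
}

#' @exportS3Method base::print
print.feature_weight_table <- function(x, ...) {
  cat(sprintf("feature_weight_table: %d features, %d folds, max weight %s\n",
              length(x$weights), x$n_folds,
              if (length(x$weights)) max(x$weights) else "NA"))
  print(utils::head(x$weights, 10))
  invisible(x)
}

#' Sweep the weight threshold
#'
#' For every threshold k = 1 .. max observed weight, the candidate panel is
#' all features with accumulated weight >= k. Sets are nested and sizes
#' non-increasing in k; successive thresholds with identical panels are all
#' retained.
#'
#' @param table A `feature_weight_table`.
#' @return A data.frame with columns `k`, `n_features` and a list column
#'   `feature_set` (feature names sorted alphabetically). Empty table ->
#'   zero rows.
#' @export
threshold_sweep <- function(table) {
  stopifnot(inherits(table, "feature_weight_table"))
  w <- table$weights
  if (length(w) == 0L)
    return(data.frame(k = integer(0), n_features = integer(0)))
  kmax <- max(w)
  sets <- lapply(seq_len(kmax), function(k) sort(names(w)[w >= k]))
  out <- data.frame(k = seq_len(kmax),
                    n_features = lengths(sets))
  out$feature_set <- sets
  out
}

#' Rank the two selectors per fold by held-out accuracy (dynamic mode)
#'
#' For each fold, trains `reference_model` on the training split restricted
#' to each selector's fold selection and scores accuracy on the held-out
#' split; the higher-accuracy selector receives weight 2, the other 1. An
#' exact tie, or an empty selection for one selector, resolves to
#' (lasso = 2, mrmr = 1); every such resolution is recorded in the returned
#' `tie_log` attribute.
#'
#' @param ds An [omics_dataset()].
#' @param plan The fold plan used for `selections`.
#' @param selections Output of [run_fold_selections()].
#' @param prep A [preprocess_spec()].
#' @param reference_model Model name used for ranking (default `"LR"`).
#' @param random_state RNG seed for the reference model fits.
#' @return List of per-fold [rank_assignment()]s (fold order), with a
#'   `tie_log` character attribute.
#' @export
dynamic_rank_per_fold <- function(ds, plan, selections,
                                  prep = preprocess_spec(),
                                  reference_model = "LR",
                                  random_state = 0L) {
  folds <- seq_len(plan$n_folds) - 1L
  log <- character(0)
  out <- lapply(folds, function(fold) {
    acc <- vapply(c("lasso", "mrmr"), function(m) {
      s <- Filter(function(x) x$method == m && x$fold_index == fold,
                  selections)[[1]]
      if (length(s$feature_names) == 0L) return(NA_real_)
      fold_accuracy(ds, s$feature_names, reference_model, plan, fold,
                    prep, random_state)
    }, numeric(1))
    if (anyNA(acc)) {
      log <<- c(log, sprintf(
        "fold %d: empty %s selection, defaulting to lasso=2", fold,
        names(acc)[is.na(acc)][1]))
      return(rank_assignment(2L, 1L))
    }
    if (acc["lasso"] == acc["mrmr"]) {
      log <<- c(log, sprintf("fold %d: tie at %.4f, lasso=2 by convention",
                             fold, acc["lasso"]))
      return(rank_assignment(2L, 1L))
    }
    if (acc["lasso"] > acc["mrmr"]) rank_assignment(2L, 1L)
    else rank_assignment(1L, 2L)
  })
  attr(out, "tie_log") <- log
  out
}

# Accuracy of one model on one fold's held-out split, feature-restricted.
fold_accuracy <- function(ds, features, model, plan, fold, prep,
                          random_state) {
  tr <- train_indices(plan, fold)
  te <- test_indices(plan, fold)
  fj <- match(features, ds$feature_names)
  Xtr <- ds$values[tr, fj, drop = FALSE]
  Xte <- ds$values[te, fj, drop = FALSE]
  std <- NULL
  if (ds$value_kind == "continuous" && isTRUE(prep$standardize))
    std <- standardize_fit(Xtr)
  pred <- fit_predict_model(model, Xtr, ds$labels[tr], Xte, std,
                            random_state)
  mean(pred == ds$labels[te])
}
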