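#' Run the full feature-selection-and-weighting pipeline
#'
#' End to end: plan stratified folds; run LASSO and mRMR on every training
#' split; accumulate rank weights under both static assignments
#' (lasso=2/mrmr=1 and lasso=1/mrmr=2) or under per-fold dynamic ranking;
#' sweep the weight threshold; score every candidate panel with the
#' requested models under the same folds; and pick the smallest panel with
#' the highest mean accuracy.
#'
#' With `holdout_fraction > 0`, a stratified holdout split is carved off
#' first and never touched by selection or sweep evaluation; the winning
#' panel and model are then refit on the development set and scored once on
#' the holdout, giving an unbiased estimate (`holdout_accuracy`).
#'
#' @param ds An [omics_dataset()].
#' @param n_folds Number of CV folds (default 5).
#' @param seed Seed for the fold plan and holdout split (default 0).
#' @param cfg A [selector_config()].
#' @param prep A [preprocess_spec()].
#' @param assignment_mode `"static"` (both rank assignments, the default)
#'   or `"dynamic"` (per-fold ranking by held-out accuracy of a reference
#'   model).
#' @param models Model names to evaluate (default all six).
#' @param random_state Seed for every classifier fit (default 0).
#' @param holdout_fraction Fraction reserved for the untouched holdout
#'   (0 disables; 0.2 is typical when enabled).
#' @param reference_model Reference model for dynamic ranking.
#' @return A `pipeline_result` list: `fold_plan`, `selections`,
#'   `weight_tables`, `sweeps`, `report` (sweep report), `best`
#'   ([select_best()] result), and when a holdout is used,
#'   `holdout_accuracy`, `holdout_majority_share` and `holdout_ids`.
#' @export
run_pipeline <- function(ds, n_folds = 5L, seed = 0L,
                         cfg = selector_config(),
                         prep = preprocess_spec(),
                         assignment_mode = c("static", "dynamic"),
                         models = MODEL_NAMES, random_state = 0L,
                         holdout_fraction = 0,
                         reference_model = "LR") {
  assignment_mode <- match.arg(assignment_mode)
  holdout <- NULL
  full_ds <- ds
  if (holdout_fraction > 0) {
    split <- stratified_holdout(ds$labels, holdout_fraction, seed)
    holdout <- split$holdout
    ds <- subset_samples(ds, split$dev)
  }
  plan <- make_fold_plan(ds$labels, n_folds, seed)
  selections <- run_fold_selections(ds, plan, cfg, prep)
  if (assignment_mode == "static") {
    assignments <- list(rank_assignment(2L, 1L), rank_assignment(1L, 2L))
  } else {
    assignments <- list(dynamic_rank_per_fold(ds, plan, selections, prep,
                                              reference_model, random_state))
  }
  weight_tables <- list()
  sweeps <- list()
  for (a in assignments) {
    lab <- if (inherits(a, "rank_assignment")) assignment_label(a)
           else "dynamic"
    wt <- accumulate_weights(selections, a)
    weight_tables[[lab]] <- wt
    sweeps[[lab]] <- threshold_sweep(wt)
  }
  report <- full_sweep_evaluation(ds, plan, sweeps, models, prep,
                                  random_state)
  best <- select_best(report)
  res <- list(fold_plan = plan, selections = selections,
              weight_tables = weight_tables, sweeps = sweeps,
              report = report, best = best,
              assignment_mode = assignment_mode)
  if (!is.null(holdout)) {
    ytr <- ds$labels
    fj <- match(best$feature_names, full_ds$feature_names)
    Xtr <- full_ds$values[setdiff(seq_len(nrow(full_ds$values)),
                                  holdout), fj, drop = FALSE]
    Xte <- full_ds$values[holdout, fj, drop = FALSE]
    std <- NULL
    if (full_ds$value_kind == "continuous" && isTRUE(prep$standardize))
      std <- standardize_fit(Xtr)
    pred <- fit_predict_model(best$model, Xtr, ytr, Xte, std, random_state)
    res$holdout_accuracy <- mean(pred == full_ds$labels[holdout])
    res$holdout_majority_share <-
      max(table(full_ds$labels[holdout])) / length(holdout)
    res$holdout_ids <- full_ds$sample_ids[holdout]
  }
  class(res) <- "pipeline_result"
  res
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  %d sweep rows x %d models (%s mode)\n",
              nrow(x$report),
              length(setdiff(colnames(x$report),
                             c("assignment", "k", "n_features",
                               "feature_set"))),
              x$assignment_mode))
  print(x$best)
  if (!is.null(x$holdout_accuracy))
    cat(sprintf("  holdout accuracy: %.3f (majority share %.3f)\n",
                x$holdout_accuracy, x$holdout_majority_share))
  invisible(x)
}

# Stratified dev/holdout split: round(fraction * class count) per class.
stratified_holdout <- function(labels, fraction, seed) {
  with_seed(seed + 1L, {
    hold <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      nh <- max(1L, round(fraction * length(idx)))
      hold <- c(hold, sort(idx[sample.int(length(idx), nh)]))
    }
    list(holdout = sort(hold),
         dev = setdiff(seq_along(labels), hold))
  })
}

subset_samples <- function(ds, idx) {
  omics_dataset(ds$values[idx, , drop = FALSE], ds$labels[idx],
                feature_names = ds$feature_names,
                sample_ids = ds$sample_ids[idx],
                value_kind = ds$value_kind,
                label_mapping = ds$label_mapping)
}
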