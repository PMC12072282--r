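#' Confusion counts
#'
#' @param TP,TN,FP,FN Nonnegative integer counts; class 1 is "positive".
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(v), class = "confusion_counts")
}

#' Classification accuracy
#'
#' ACC = (TP + TN) / (TP + TN + FP + FN): the proportion of correctly
#' classified samples.
#'
#' @param c A [confusion_counts()] object.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("no evaluated samples (all counts zero)")
  (c$TP + c$TN) / total
}

confusion_from_predictions <- function(truth, pred) {
  confusion_counts(TP = sum(truth == 1L & pred == 1L),
                   TN = sum(truth == 0L & pred == 0L),
                   FP = sum(truth == 0L & pred == 1L),
                   FN = sum(truth == 1L & pred == 0L))
}

#' Soft-voting combination
#'
#' Sums the five members' class-probability vectors and predicts the class
#' with the larger sum; an exact tie resolves to class 0.
#'
#' @param member_probabilities List of five numeric length-2 vectors (class
#'   0 then class 1 probability), each summing to 1 within tolerance.
#' @return Predicted class, 0 or 1.
#' @export
soft_vote <- function(member_probabilities) {
  if (length(member_probabilities) != length(VOTING_MEMBERS))
    stop("expected ", length(VOTING_MEMBERS), " member probability vectors, got ",
         length(member_probabilities))
  for (p in member_probabilities) {
    if (length(p) != 2L || abs(sum(p) - 1) > 1e-6)
      stop("each member must supply a length-2 probability vector summing to 1")
  }
  s <- Reduce(`+`, member_probabilities)
  if (s[2] > s[1]) 1L else 0L
}

#' Cross-validated accuracy of a feature subset
#'
#' For each fold of the plan: fit the model on the training split restricted
#' to `features` (preprocessing fit on the training split only), predict the
#' held-out split, and compute the accuracy from the confusion counts. The
#' returned `mean_accuracy` is the unweighted mean of the fold accuracies;
#' `pooled_accuracy` (accuracy of the pooled confusion counts) is also
#' reported since fold sizes may differ by one.
#'
#' @param ds An [omics_dataset()].
#' @param features Character vector of feature names (non-empty, all
#'   present in `ds`).
#' @param model A [model_spec()] or model name.
#' @param plan A [make_fold_plan()] plan.
#' @param prep A [preprocess_spec()].
#' @return A `subset_evaluation` list: `mean_accuracy`, `fold_accuracies`,
#'   `pooled_accuracy`.
#' @export
evaluate_subset <- function(ds, features, model, plan,
                            prep = preprocess_spec()) {
  if (is.character(model)) model <- model_spec(model)
  if (length(features) == 0L) stop("empty feature set")
  fj <- match(features, ds$feature_names)
  if (anyNA(fj))
    stop("features not in dataset: ",
         paste(features[is.na(fj)], collapse = ", "))
  accs <- numeric(plan$n_folds)
  pooled <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (fold in seq_len(plan$n_folds) - 1L) {
    tr <- train_indices(plan, fold)
    te <- test_indices(plan, fold)
    ytr <- ds$labels[tr]
    if (length(unique(ytr)) < 2L)
      stop("fold ", fold, ": training split contains a single class")
    Xtr <- ds$values[tr, fj, drop = FALSE]
    Xte <- ds$values[te, fj, drop = FALSE]
    std <- NULL
    if (ds$value_kind == "continuous" && isTRUE(prep$standardize))
      std <- standardize_fit(Xtr)
    pred <- fit_predict_model(model$name, Xtr, ytr, Xte, std,
                              model$random_state, model$hyperparameters)
    cc <- confusion_from_predictions(ds$labels[te], pred)
    accs[fold + 1L] <- accuracy(cc)
    pooled <- pooled + unlist(cc)[c("TP", "TN", "FP", "FN")]
  }
  structure(list(mean_accuracy = mean(accs), fold_accuracies = accs,
                 pooled_accuracy = unname((pooled["TP"] + pooled["TN"]) /
                                            sum(pooled))),
            class = "subset_evaluation")
}

#' Score every sweep row with every model
#'
#' Builds the sweep report: one row per (assignment, threshold k) with the
#' candidate panel and each model's cross-validated mean accuracy.
#' Identical panels arising at different thresholds are evaluated once and
#' share their accuracies.
#'
#' @param ds An [omics_dataset()].
#' @param plan The fold plan (the same one used for feature selection).
#' @param sweeps Named list, one [threshold_sweep()] data.frame per
#'   assignment label.
#' @param models Character vector of model names (default all six).
#' @param prep A [preprocess_spec()].
#' @param random_state Seed for every model fit (default 0).
#' @return A `sweep_report` data.frame: `assignment`, `k`, `n_features`,
#'   list column `feature_set`, and one mean-accuracy column per model.
#' @export
full_sweep_evaluation <- function(ds, plan, sweeps, models = MODEL_NAMES,
                                  prep = preprocess_spec(),
                                  random_state = 0L) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (a in names(sweeps)) {
    sw <- sweeps[[a]]
    for (i in seq_len(nrow(sw))) {
      fs <- sw$feature_set[[i]]
      row <- list(assignment = a, k = sw$k[i], n_features = sw$n_features[i])
      for (m in models) {
        key <- paste(m, paste(fs, collapse = "\r"), sep = "\n")
        if (is.null(cache[[key]])) {
          acc <- tryCatch(
            evaluate_subset(ds, fs, model_spec(m, random_state), plan,
                            prep)$mean_accuracy,
            error = function(e) stop("assignment ", a, ", k=", sw$k[i],
                                     ", model ", m, ": ",
                                     conditionMessage(e), call. = FALSE))
          assign(key, acc, envir = cache)
        }
        row[[m]] <- cache[[key]]
      }
      row$feature_set <- list(fs)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(r[setdiff(names(r), "feature_set")],
                    stringsAsFactors = FALSE, check.names = FALSE)
    d$feature_set <- r$feature_set
    d
  }))
  class(out) <- c("sweep_report", class(out))
  out
}

#' Select the best sweep cell
#'
#' Maximizes mean accuracy over all (assignment, k, model) cells; ties are
#' resolved by the smallest panel (largest dimensionality reduction), then
#' the larger threshold k, then model order (SVM, LR, KNN, RF, AdaBoost,
#' Voting), then assignment lasso2_mrmr1 before lasso1_mrmr2. Every applied
#' tie-break is recorded in `tie_break_log`.
#'
#' @param report A [full_sweep_evaluation()] report.
#' @return A `best_result` list: `assignment`, `k`, `model`,
#'   `feature_names`, `mean_accuracy`, `n_features`, `tie_break_log`.
#' @export
select_best <- function(report) {
  if (is.null(report) || nrow(report) == 0L) stop("empty sweep report")
  model_cols <- intersect(MODEL_ORDER_TIEBREAK, colnames(report))
  cells <- do.call(rbind, lapply(model_cols, function(m) {
    data.frame(assignment = report$assignment, k = report$k,
               n_features = report$n_features, model = m,
               mean_accuracy = report[[m]], row = seq_len(nrow(report)),
               stringsAsFactors = FALSE)
  }))
  log <- character(0)
  best <- cells[cells$mean_accuracy == max(cells$mean_accuracy), ]
  if (nrow(best) > 1L) {
    log <- c(log, sprintf("%d cells tie at accuracy %.6f; minimizing panel size",
                          nrow(best), best$mean_accuracy[1]))
    best <- best[best$n_features == min(best$n_features), ]
  }
  if (nrow(best) > 1L) {
    log <- c(log, sprintf("%d cells tie at %d features; preferring larger k",
                          nrow(best), best$n_features[1]))
    best <- best[best$k == max(best$k), ]
  }
  if (nrow(best) > 1L) {
    log <- c(log, "tie on k; preferring model order SVM, LR, KNN, RF, AdaBoost, Voting")
    mi <- match(best$model, MODEL_ORDER_TIEBREAK)
    best <- best[mi == min(mi), ]
  }
  if (nrow(best) > 1L) {
    log <- c(log, "tie on model; preferring assignment lasso2_mrmr1")
    best <- best[order(match(best$assignment,
                             c("lasso2_mrmr1", "lasso1_mrmr2"))), ][1, ]
  }
  best <- best[1, ]
  structure(list(assignment = best$assignment, k = best$k,
                 model = best$model,
                 feature_names = report$feature_set[[best$row]],
                 mean_accuracy = best$mean_accuracy,
                 n_features = best$n_features,
                 tie_break_log = log),
            class = "best_result")
}

MODEL_ORDER_TIEBREAK <- c("SVM", "LR", "KNN", "RF", "AdaBoost", "Voting")

#' @exportS3Method base::print
print.best_result <- function(x, ...) {
  cat(sprintf("best_result: %s, k=%d, %s, %d features, mean accuracy %.3f%%\n",
              x$assignment, x$k, x$model, x$n_features,
              100 * x$mean_accuracy))
  cat("  panel:", paste(utils::head(x$feature_names, 20), collapse = ", "),
      if (x$n_features > 20) "..." else "", "\n")
  invisible(x)
}
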