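#' Clustergram data for a feature panel
#'
#' Computes everything a clustergram rendering needs, without drawing it:
#' per-feature z-scores across samples, agglomerative clustering of the
#' features with average linkage on correlation distance (1 - Pearson),
#' the dendrogram leaf order, samples grouped by class (within-class order
#' preserved), and a per-feature rank bar (rank 1 = highest accumulated
#' weight, ties by name).
#'
#' Features are canonicalized by name before clustering so the result does
#' not depend on input column order. A constant feature yields a zero
#' z-row (with a warning) and is placed at maximal correlation distance
#' (2) from every other feature.
#'
#' @param ds An [omics_dataset()].
#' @param panel Character vector of at least two feature names in `ds`.
#' @param weights Optional named weight vector (e.g.
#'   `feature_weight_table$weights`) used for the rank bar; defaults to
#'   panel order.
#' @return A `clustergram_data` list: `z_matrix` (feature x sample),
#'   `feature_order`, `feature_linkage` (an [stats::hclust] object),
#'   `sample_order`, `rank_bar`.
#' @export
clustergram <- function(ds, panel, weights = NULL) {
  stopifnot(inherits(ds, "omics_dataset"))
  panel <- as.character(panel)
  if (length(panel) < 2L) stop("panel must contain at least two features")
  fj <- match(panel, ds$feature_names)
  if (anyNA(fj))
    stop("panel features not in dataset: ",
         paste(panel[is.na(fj)], collapse = ", "))
  cano <- order(panel)                      # canonical order: by name
  panel <- panel[cano]
  fj <- fj[cano]
  M <- t(ds$values[, fj, drop = FALSE])     # features x samples
  mu <- rowMeans(M)
  sd <- apply(M, 1L, stats::sd)
  const <- sd == 0
  if (any(const)) {
    warning("constant feature(s) z-scored to zero: ",
            paste(panel[const], collapse = ", "))
    sd[const] <- 1
  }
  Z <- (M - mu) / sd
  D <- 1 - suppressWarnings(stats::cor(t(Z)))
  D[is.na(D)] <- 2                          # constant rows: maximal distance
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  smp <- order(ds$labels, seq_along(ds$labels))
  if (is.null(weights)) weights <- stats::setNames(rev(seq_along(panel)), panel)
  w <- weights[panel]
  w[is.na(w)] <- 0
  rank_bar <- stats::setNames(rank(-w, ties.method = "first"), panel)
  structure(list(z_matrix = Z, feature_order = hc$order,
                 feature_linkage = hc, sample_order = smp,
                 rank_bar = rank_bar, feature_names = panel),
            class = "clustergram_data")
}

#' Render a clustergram heatmap
#'
#' Thin base-graphics layer over [clustergram()]: heatmap of z-scores
#' (clipped to ±3 for display), features in dendrogram order, samples
#' grouped by class, with a grey rank bar. The computed data, not this
#' image, is the tested surface.
#'
#' @param cg A `clustergram_data` object.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot_clustergram <- function(cg, ...) {
  Z <- pmin(pmax(cg$z_matrix, -3), 3)
  stats::heatmap(Z[, cg$sample_order, drop = FALSE],
                 Rowv = stats::as.dendrogram(cg$feature_linkage),
                 Colv = NA, scale = "none",
                 RowSideColors = grDevices::grey(
                   1 - cg$rank_bar / max(cg$rank_bar)),
                 ...)
  invisible(cg)
}

#' Write a sweep report as TSV
#'
#' Mirrors the published sweep-table layout: one row per (assignment, k)
#' with the panel size and each model's mean accuracy as a percentage with
#' three decimals.
#'
#' @param report A [full_sweep_evaluation()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(report, path) {
  model_cols <- setdiff(colnames(report),
                        c("assignment", "k", "n_features", "feature_set"))
  out <- report[, c("assignment", "k", "n_features")]
  for (m in model_cols) out[[m]] <- sprintf("%.3f", 100 * report[[m]])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep TSV back into a report
#'
#' Inverse of [write_sweep_tsv()] up to the 3-decimal percentage formatting
#' (accuracies are returned as fractions). The feature sets are not stored
#' in the TSV and are absent from the parsed report.
#'
#' @param path TSV path.
#' @return A data.frame shaped like a sweep report (without `feature_set`).
#' @export
read_sweep_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (m in setdiff(colnames(df), c("assignment", "k", "n_features")))
    df[[m]] <- df[[m]] / 100
  df
}

#' Write a weight table as TSV
#'
#' Columns: feature_name, selection_count_lasso, selection_count_mrmr,
#' weight_21 (lasso=2/mrmr=1), weight_12 (lasso=1/mrmr=2).
#'
#' @param selections Output of [run_fold_selections()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table_tsv <- function(selections, path) {
  w21 <- accumulate_weights(selections, rank_assignment(2L, 1L))
  w12 <- accumulate_weights(selections, rank_assignment(1L, 2L))
  feats <- sort(union(names(w21$weights), names(w12$weights)))
  g <- function(v, f) ifelse(f %in% names(v), v[f], 0)
  df <- data.frame(
    feature_name = feats,
    selection_count_lasso = as.integer(g(w21$count_lasso, feats)),
    selection_count_mrmr = as.integer(g(w21$count_mrmr, feats)),
    weight_21 = as.integer(g(w21$weights, feats)),
    weight_12 = as.integer(g(w12$weights, feats)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the best result as JSON
#'
#' @param best A [select_best()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_best_json <- function(best, path) {
  jsonlite::write_json(
    list(assignment = best$assignment, k = best$k, model = best$model,
         n_features = best$n_features,
         mean_accuracy = best$mean_accuracy,
         mean_accuracy_pct = round(100 * best$mean_accuracy, 3),
         feature_names = best$feature_names,
         tie_break_log = best$tie_break_log),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-exactly: the selector
#' and preprocessing configuration, fold seed and classifier random state,
#' label mapping, package and R versions, tie-break log, and the pooled
#' accuracy of the winning panel when supplied.
#'
#' @param path Output path.
#' @param cfg A [selector_config()].
#' @param prep A [preprocess_spec()].
#' @param seed Fold-plan seed.
#' @param random_state Classifier seed.
#' @param n_folds Number of folds.
#' @param label_mapping Named 0/1 vector (from the dataset).
#' @param tie_break_log Character vector of tie-break events.
#' @param extra Named list of additional entries (e.g. pooled accuracy).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, cfg, prep, seed = 0L,
                               random_state = 0L, n_folds = 5L,
                               label_mapping = NULL,
                               tie_break_log = character(0),
                               extra = list()) {
  manifest <- c(list(
    package = "panelselect",
    package_version = as.character(utils::packageVersion("panelselect")),
    r_version = as.character(getRversion()),
    n_folds = n_folds, seed = seed, random_state = random_state,
    selector_config = unclass(cfg), preprocess = unclass(prep),
    label_mapping = as.list(label_mapping),
    tie_break_log = tie_break_log), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
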