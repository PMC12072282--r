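#' Construct an omics dataset
#'
#' The universal input container: a numeric samples x features matrix with a
#' binary class label per sample. Continuous data are intensity matrices
#' (optionally log2-transformed); binary data are 0/1 indicator matrices
#' (e.g. mutation status).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param labels Integer vector of 0/1 class codes, one per sample. By
#'   convention 0 = female, 1 = male; the mapping actually used is carried in
#'   `label_mapping`.
#' @param feature_names Character vector of unique feature names; defaults to
#'   the column names of `values`.
#' @param sample_ids Character vector of sample identifiers; defaults to row
#'   names or `S1..Sn`.
#' @param value_kind `"continuous"` or `"binary"`. Binary matrices must
#'   contain only 0 and 1.
#' @param label_mapping Named integer vector recording how original label
#'   strings map onto 0/1.
#'
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(values, labels, feature_names = colnames(values),
                          sample_ids = rownames(values),
                          value_kind = c("continuous", "binary"),
                          label_mapping = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  feature_names <- as.character(feature_names)
  sample_ids <- as.character(sample_ids)
  if (length(feature_names) != p)
    stop("length(feature_names) != ncol(values)")
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (length(sample_ids) != n) stop("length(sample_ids) != nrow(values)")
  labels <- as.integer(labels)
  if (length(labels) != n) stop("length(labels) != nrow(values)")
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) != 2L)
    stop("labels must contain exactly the two classes 0 and 1")
  if (value_kind == "binary" && !all(values %in% c(0, 1)))
    stop("binary dataset contains entries outside {0, 1}")
  if (anyNA(values)) stop("'values' contains missing entries")
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, labels = labels, feature_names = feature_names,
         sample_ids = sample_ids, value_kind = value_kind,
         label_mapping = label_mapping),
    class = "omics_dataset"
  )
}

#' @exportS3Method base::print
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  cat(sprintf("  class 0: %d  class 1: %d\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  if (!is.null(x$label_mapping)) {
    cat("  label mapping:",
        paste(sprintf("%s=%d", names(x$label_mapping), x$label_mapping),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' Read a feature table from CSV/TSV
#'
#' Parses a delimited text file into an [omics_dataset]. The table must hold
#' one label column (exactly two distinct values; mapped onto 0/1 by sorted
#' order unless `label_levels` overrides) and numeric feature columns. An
#' optional first column named `sample_id` (or an empty header) supplies
#' sample identifiers.
#'
#' @param path File path.
#' @param label_column Name of the label column (for `features_as_rows`, the
#'   label row).
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension
#'   (`.tsv` tab, otherwise comma).
#' @param orientation `"samples_as_rows"` (default) or `"features_as_rows"`
#'   (features in rows, samples in columns, feature names in the first
#'   column).
#' @param value_kind Passed to [omics_dataset()].
#' @param label_levels Optional length-2 character vector fixing which label
#'   string maps to 0 and which to 1 (in that order).
#'
#' @return An `omics_dataset`; the label mapping is stored in
#'   `$label_mapping`.
#' @export
read_feature_table <- function(path, label_column,
                               delimiter = NULL,
                               orientation = c("samples_as_rows",
                                               "features_as_rows"),
                               value_kind = c("continuous", "binary"),
                               label_levels = NULL) {
  orientation <- match.arg(orientation)
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "")
  if (orientation == "features_as_rows") {
    rn <- raw[[1L]]
    if (anyDuplicated(rn))
      stop("duplicate row names in features_as_rows table: ",
           paste(unique(rn[duplicated(rn)]), collapse = ", "))
    mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
    raw <- as.data.frame(mat, stringsAsFactors = FALSE)
    colnames(raw) <- rn
    raw <- cbind(sample_id = rownames(mat), raw, stringsAsFactors = FALSE)
    rownames(raw) <- NULL
  }
  cn <- colnames(raw)
  if (!label_column %in% cn)
    stop("label column '", label_column, "' not found; columns are: ",
         paste(utils::head(cn, 10), collapse = ", "))
  id_col <- which(cn %in% c("", "sample_id"))[1]
  sample_ids <- if (!is.na(id_col)) raw[[id_col]] else paste0("S", seq_len(nrow(raw)))
  lab_raw <- raw[[label_column]]
  lv <- sort(unique(lab_raw))
  if (length(lv) != 2L)
    stop("label column '", label_column, "' has ", length(lv),
         " distinct values (more than two classes or fewer): ",
         paste(lv, collapse = ", "))
  if (!is.null(label_levels)) {
    if (!setequal(label_levels, lv))
      stop("label_levels ", paste(label_levels, collapse = "/"),
           " do not match observed labels ", paste(lv, collapse = "/"))
    lv <- label_levels
  }
  mapping <- stats::setNames(c(0L, 1L), lv)
  labels <- mapping[lab_raw]
  drop <- c(label_column, if (!is.na(id_col)) cn[id_col])
  feat <- raw[, setdiff(cn, drop), drop = FALSE]
  vals <- matrix(NA_real_, nrow(feat), ncol(feat),
                 dimnames = list(sample_ids, colnames(feat)))
  for (j in seq_along(feat)) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(v) & !is.na(feat[[j]]))
    if (length(bad))
      stop("non-numeric value '", feat[[j]][bad[1]], "' in feature '",
           colnames(feat)[j], "', row ", bad[1])
    vals[, j] <- v
  }
  if (anyDuplicated(colnames(feat)))
    stop("duplicate feature names: ",
         paste(unique(colnames(feat)[duplicated(colnames(feat))]),
               collapse = ", "))
  omics_dataset(vals, labels, value_kind = value_kind,
                label_mapping = mapping)
}

#' Write an omics dataset to CSV/TSV
#'
#' Inverse of [read_feature_table()] for the `samples_as_rows` orientation:
#' one `sample_id` column, one label column (original label strings if a
#' mapping is recorded, else the 0/1 codes), then the feature columns, with a
#' header row.
#'
#' @param ds An `omics_dataset`.
#' @param path Output path.
#' @param label_column Header for the label column.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, path, label_column = "label",
                                delimiter = NULL) {
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  lab <- ds$labels
  if (!is.null(ds$label_mapping))
    lab <- names(ds$label_mapping)[match(ds$labels, ds$label_mapping)]
  df <- data.frame(sample_id = ds$sample_ids, lab, ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[2] <- label_column
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Log2-transform a continuous dataset
#'
#' Replaces every entry x by log2(x + pseudocount). The pseudocount guards
#' zero intensities; it must be positive when the matrix contains zeros.
#'
#' @param ds A continuous `omics_dataset`.
#' @param pseudocount Nonnegative shift added before the log (default 1).
#' @return The transformed `omics_dataset`.
#' @export
log2_transform <- function(ds, pseudocount = 1) {
  stopifnot(inherits(ds, "omics_dataset"))
  if (ds$value_kind != "continuous")
    stop("log2_transform applies to continuous data only")
  shifted <- ds$values + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "log2 of nonpositive value at sample '%s', feature '%s' (%g + %g <= 0)",
      ds$sample_ids[bad[1]], ds$feature_names[bad[2]],
      ds$values[bad[1], bad[2]], pseudocount))
  }
  ds$values <- log2(shifted)
  ds
}

#' Preprocessing specification
#'
#' @param log2 Apply [log2_transform()] to the whole matrix up front.
#' @param pseudocount Shift used by the log2 transform.
#' @param standardize Per-feature z-scoring inside cross-validation, with
#'   mean and SD fit on the training split only and applied to the held-out
#'   split (no leakage). Applied before LASSO and before the scale-sensitive
#'   classifiers (SVM, KNN, LR); tree ensembles see raw values. Ignored for
#'   binary data.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(log2 = FALSE, pseudocount = 1,
                            standardize = TRUE) {
  stopifnot(pseudocount >= 0)
  structure(list(log2 = log2, pseudocount = pseudocount,
                 standardize = standardize),
            class = "preprocess_spec")
}

# Fit/apply helpers for within-fold z-scoring. Constant features get sd 1 so
# they pass through as zeros after centering.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mean, "-"), 2L, fit$sd, "/")
}

#' Plan stratified cross-validation folds
#'
#' Deterministically assigns every sample to one of `n_folds` folds such that
#' each fold's per-class count deviates from exact proportionality by at most
#' one sample and overall fold sizes differ by at most one. Within each
#' class, samples are shuffled with the seed; each class's remainder samples
#' are dealt to the currently smallest folds so the totals stay balanced.
#'
#' @param labels Integer 0/1 class codes.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed (default 0); the same (labels, n_folds, seed) always
#'   yields the same plan.
#' @return A `fold_plan`: list with `n_folds`, `seed` and `assignments`
#'   (per-sample fold index in 0..n_folds-1).
#' @export
make_fold_plan <- function(labels, n_folds = 5L, seed = 0L) {
  labels <- as.integer(labels)
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("smallest class has ", min(counts),
         " samples; need at least n_folds = ", n_folds)
  assignments <- integer(length(labels))
  totals <- integer(n_folds)
  with_seed(seed, {
    # larger classes first so their remainders are placed before the
    # fold totals are constrained by the smaller class
    for (cl in names(sort(counts, decreasing = TRUE))) {
      idx <- which(labels == as.integer(cl))
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% n_folds
      rem <- length(idx) %% n_folds
      per_fold <- rep(base, n_folds)
      if (rem > 0) {
        extra <- order(totals, seq_len(n_folds))[seq_len(rem)]
        per_fold[extra] <- per_fold[extra] + 1L
      }
      fold_of <- rep.int(seq_len(n_folds), per_fold)
      assignments[idx] <- fold_of - 1L
      totals <- totals + per_fold
    }
  })
  structure(list(n_folds = n_folds, seed = as.integer(seed),
                 assignments = assignments),
            class = "fold_plan")
}

#' @exportS3Method base::print
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds, seed %d, %d samples\n",
              x$n_folds, x$seed, length(x$assignments)))
  print(table(fold = x$assignments))
  invisible(x)
}

# Training-split sample indices for fold i (0-based fold index).
train_indices <- function(plan, fold) which(plan$assignments != fold)
test_indices <- function(plan, fold) which(plan$assignments == fold)

# Evaluate expr with a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
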