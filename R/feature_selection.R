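#' Selector configuration
#'
#' Settings shared by the two base selectors.
#'
#' @param lasso_alpha L1 penalty strength (the `alpha` of the usual sparse
#'   regression formulation, glmnet's `lambda`). Default 1.0; 0.01 is the
#'   recommended override for strongly correlated feature sets.
#' @param lasso_max_iter Coordinate-descent iteration cap.
#' @param mrmr_k Number of features the greedy mRMR selector returns per
#'   fold (default 50; truncated to the number of features).
#' @param relevance Relevance estimator; one-way F statistic of the feature
#'   grouped by the class label (the only option).
#' @param redundancy Redundancy estimator; absolute Pearson correlation with
#'   already-selected features (the only option).
#' @param scheme How relevance and mean redundancy combine at each greedy
#'   step: `"quotient"` (FCQ, default) divides, `"difference"` subtracts.
#' @param redundancy_floor Lower floor on mean absolute correlation in the
#'   quotient scheme, guarding division by zero.
#' @return A `selector_config` list.
#' @export
selector_config <- function(lasso_alpha = 1.0, lasso_max_iter = 100000L,
                            mrmr_k = 50L,
                            relevance = "f_stat",
                            redundancy = "abs_pearson",
                            scheme = c("quotient", "difference"),
                            redundancy_floor = 1e-6) {
  scheme <- match.arg(scheme)
  relevance <- match.arg(relevance)
  redundancy <- match.arg(redundancy)
  stopifnot(lasso_alpha > 0, mrmr_k >= 1)
  structure(list(lasso_alpha = lasso_alpha,
                 lasso_max_iter = as.integer(lasso_max_iter),
                 mrmr_k = as.integer(mrmr_k),
                 relevance = relevance, redundancy = redundancy,
                 scheme = scheme, redundancy_floor = redundancy_floor),
            class = "selector_config")
}

selector_output <- function(method, fold_index, selected, scores,
                            feature_names) {
  structure(list(method = method, fold_index = as.integer(fold_index),
                 selected = selected, scores = scores,
                 feature_names = feature_names[selected]),
            class = "selector_output")
}

#' LASSO feature selection
#'
#' Fits an L1-penalized linear model of the 0/1 label on the feature matrix
#' at penalty `cfg$lasso_alpha` and returns its support: the features with
#' nonzero coefficients, ordered by |coefficient| descending (ties by
#' ascending column index). Continuous inputs are expected standardized
#' (within-fold z-scores); binary indicator matrices are used as-is.
#'
#' @param X_train Numeric matrix (training split).
#' @param y_train 0/1 labels.
#' @param cfg A [selector_config()].
#' @param fold_index Fold identifier carried into the output.
#' @return A `selector_output` with `selected` (column indices), `scores`
#'   (|coefficient|, all > 0) and `feature_names`.
#' @export
lasso_select <- function(X_train, y_train, cfg = selector_config(),
                         fold_index = NA_integer_) {
  y_train <- as.numeric(y_train)
  if (length(unique(y_train)) < 2L)
    stop("y_train contains a single class")
  X <- as.matrix(X_train)
  padded <- FALSE
  if (ncol(X) == 1L) {           # glmnet needs >= 2 columns
    X <- cbind(X, 0)
    padded <- TRUE
  }
  # decreasing path ending at the target penalty keeps coordinate descent
  # warm-started and deterministic
  lam <- cfg$lasso_alpha * c(8, 4, 2, 1)
  fit <- glmnet::glmnet(X, y_train, family = "gaussian", alpha = 1,
                        lambda = lam, standardize = FALSE,
                        maxit = cfg$lasso_max_iter)
  if (fit$jerr != 0)
    warning("glmnet did not fully converge (jerr=", fit$jerr,
            "); returning current support")
  beta <- as.numeric(fit$beta[, length(lam)])
  if (padded) beta <- beta[1L]
  nz <- which(beta != 0)
  ord <- order(-abs(beta[nz]), nz)
  sel <- nz[ord]
  fn <- colnames(X_train)
  if (is.null(fn)) fn <- paste0("F", seq_len(ncol(as.matrix(X_train))))
  selector_output("lasso", fold_index, sel, abs(beta[sel]), fn)
}

# One-way F statistic of each column of X grouped by binary y, vectorized.
# Zero-variance columns get relevance 0 by convention; perfect separators
# (zero within-group variance, nonzero between) get Inf.
f_stat_relevance <- function(X, y) {
  y <- as.integer(y)
  n <- nrow(X)
  n0 <- sum(y == 0L)
  n1 <- n - n0
  m0 <- colMeans(X[y == 0L, , drop = FALSE])
  m1 <- colMeans(X[y == 1L, , drop = FALSE])
  gm <- colMeans(X)
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  sst <- colSums(sweep(X, 2L, gm, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2L))
  f[sst == 0] <- 0          # constant feature: relevance 0, never preferred
  f[ssw == 0 & ssb > 0] <- Inf
  f
}

#' Greedy mRMR feature selection (FCQ)
#'
#' Forward selection of `k` features. Step 1 picks the feature with maximal
#' relevance (one-way F statistic against the label). Each later step picks
#' the feature maximizing relevance / mean(|Pearson correlation| with the
#' already-selected set) under the quotient scheme (the difference scheme
#' subtracts the mean redundancy instead). Mean redundancy is floored at
#' `cfg$redundancy_floor`. All ties break by ascending column index.
#'
#' @param X_train Numeric matrix (training split).
#' @param y_train 0/1 labels.
#' @param k Number of features to return; truncated to `ncol(X_train)` with
#'   a warning.
#' @param cfg A [selector_config()].
#' @param fold_index Fold identifier carried into the output.
#' @return A `selector_output`; `selected` is in selection order and
#'   `scores` holds the greedy criterion value at each step.
#' @export
mrmr_select <- function(X_train, y_train, k = NULL,
                        cfg = selector_config(), fold_index = NA_integer_) {
  X <- as.matrix(X_train)
  if (length(unique(y_train)) < 2L)
    stop("y_train contains a single class")
  if (is.null(k)) k <- cfg$mrmr_k
  p <- ncol(X)
  if (k > p) {
    warning("k = ", k, " exceeds n_features = ", p, "; truncating")
    k <- p
  }
  rel <- f_stat_relevance(X, y_train)
  sel <- integer(0)
  scores <- numeric(0)
  # running sum of |cor| with selected features, per candidate
  red_sum <- numeric(p)
  csd <- apply(X, 2L, stats::sd)
  remaining <- rep(TRUE, p)
  for (step in seq_len(k)) {
    if (step == 1L) {
      crit <- rel
    } else {
      mean_red <- red_sum / length(sel)
      if (cfg$scheme == "quotient") {
        crit <- rel / pmax(mean_red, cfg$redundancy_floor)
      } else {
        crit <- rel - mean_red
      }
    }
    crit[!remaining] <- -Inf
    pick <- as.integer(which(crit == max(crit))[1L])  # ties by ascending index
    sel <- c(sel, pick)
    scores <- c(scores, unname(crit[pick]))
    remaining[pick] <- FALSE
    if (step < k) {
      r <- rep(0, p)
      ok <- csd > 0 & csd[pick] > 0
      if (any(ok))
        r[ok] <- abs(suppressWarnings(
          stats::cor(X[, ok, drop = FALSE], X[, pick])))
      r[is.na(r)] <- 0
      red_sum <- red_sum + r
    }
  }
  fn <- colnames(X)
  if (is.null(fn)) fn <- paste0("F", seq_len(p))
  selector_output("mrmr", fold_index, sel, scores, fn)
}

#' Export per-fold selections as a tidy table
#'
#' @param selections List of `selector_output` objects.
#' @return A data.frame with columns fold, method, rank, feature_name,
#'   score.
#' @export
selections_table <- function(selections) {
  do.call(rbind, lapply(selections, function(s) {
    if (length(s$selected) == 0L) return(NULL)
    data.frame(fold = s$fold_index, method = s$method,
               rank = seq_along(s$selected),
               feature_name = s$feature_names,
               score = s$scores, stringsAsFactors = FALSE)
  }))
}
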