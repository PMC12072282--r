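# Independent oracles and fixture builders shared across test files.

# Minimal selector_output stand-in: accumulate_weights and threshold_sweep
# only consume method, fold_index and feature_names.
make_selection <- function(method, fold, feature_names) {
  structure(list(method = method, fold_index = as.integer(fold),
                 selected = seq_along(feature_names),
                 scores = rep(1, length(feature_names)),
                 feature_names = feature_names),
            class = "selector_output")
}

# Naive double-loop weight accumulation: for every feature, walk every
# selection and add the method weight when present.
naive_accumulate <- function(selections, w_lasso, w_mrmr) {
  feats <- sort(unique(unlist(lapply(selections, `[[`, "feature_names"))))
  w <- setNames(numeric(length(feats)), feats)
  for (f in feats) {
    for (s in selections) {
      if (f %in% s$feature_names)
        w[f] <- w[f] + if (s$method == "lasso") w_lasso else w_mrmr
    }
  }
  w
}

# Exhaustive mRMR re-evaluation: at every step recompute the criterion for
# every remaining candidate from scratch (aov-based F, pairwise cor).
mrmr_oracle <- function(X, y, k, scheme = "quotient", floor = 1e-6) {
  p <- ncol(X)
  f_one <- function(j) {
    if (stats::sd(X[, j]) == 0) return(0)
    a <- stats::anova(stats::lm(X[, j] ~ factor(y)))
    f <- a[["F value"]][1]
    if (is.nan(f)) Inf else f
  }
  rel <- vapply(seq_len(p), f_one, numeric(1))
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(j) {
      if (step == 1) return(rel[j])
      red <- mean(vapply(sel, function(s) {
        if (stats::sd(X[, j]) == 0 || stats::sd(X[, s]) == 0) return(0)
        abs(stats::cor(X[, j], X[, s]))
      }, numeric(1)))
      if (scheme == "quotient") rel[j] / max(red, floor) else rel[j] - red
    }, numeric(1))
    sel <- c(sel, cand[which(crit == max(crit))[1]])
  }
  sel
}

# Random fold-selection instances for the weight-accumulation oracle checks.
random_selections <- function(n_folds, feature_pool) {
  sels <- list()
  for (fold in seq_len(n_folds) - 1L) {
    for (m in c("lasso", "mrmr")) {
      nf <- sample(0:length(feature_pool), 1)
      feats <- if (nf > 0) sample(feature_pool, nf) else character(0)
      sels[[length(sels) + 1L]] <- make_selection(m, fold, feats)
    }
  }
  sels
}

# Small deterministic continuous dataset with one perfectly separating
# feature, for classifier sanity checks.
perfect_feature_dataset <- function(n = 40, p = 5, seed = 7) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- y * 4 + rnorm(n, sd = 0.1)
  colnames(X) <- paste0("F", seq_len(p))
  omics_dataset(X, y, value_kind = "continuous")
}
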