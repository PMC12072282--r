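#' Specification for synthetic continuous omics data
#'
#' Emulates the shape of high-dimensional intensity matrices: a minority of
#' "planted" informative features carry a class-dependent mean shift
#' (in SD units); all features share Gaussian noise, optionally correlated
#' in blocks. The class imbalance default (68% class 1) mirrors a typical
#' clinical cohort with a roughly 2:1 male/female ratio.
#'
#' @param n_samples,n_features,n_informative Dimensions; `n_informative <=
#'   n_features`.
#' @param class_share Fraction of samples in class 1 (default 0.68).
#' @param effect_size Mean shift of each informative feature between the
#'   classes, in units of the feature SD (default 2.0).
#' @param n_corr_blocks Number of equal blocks the informative features are
#'   split into that share a latent factor (0 = independent features, the
#'   default).
#' @param block_rho Within-block correlation in \[0, 1).
#' @param noise_sd Feature SD (default 1).
#' @param lognormal If `TRUE`, entries are exponentiated so the matrix holds
#'   strictly positive intensities suitable for the log2 path.
#' @return A `continuous_spec` list.
#' @export
continuous_spec <- function(n_samples, n_features, n_informative,
                            class_share = 0.68, effect_size = 2.0,
                            n_corr_blocks = 0L, block_rho = 0,
                            noise_sd = 1, lognormal = FALSE) {
  stopifnot(n_informative <= n_features, n_informative >= 0,
            class_share > 0, class_share < 1,
            block_rho >= 0, block_rho < 1, noise_sd > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_share = class_share, effect_size = effect_size,
                 n_corr_blocks = as.integer(n_corr_blocks),
                 block_rho = block_rho, noise_sd = noise_sd,
                 lognormal = lognormal),
            class = "continuous_spec")
}

#' Specification for synthetic binary (mutation-style) data
#'
#' Features are Bernoulli indicators (0 = not mutated, 1 = mutated).
#' Informative features differ in mutation rate between the classes by
#' `informative_delta`.
#'
#' @param n_samples,n_features,n_informative Dimensions.
#' @param baseline_rate Mutation rate of uninformative features and of
#'   class 0 on informative features.
#' @param informative_delta Rate difference added for class 1 on
#'   informative features; `baseline_rate + informative_delta` must lie in
#'   \[0, 1\].
#' @param class_share Fraction of samples in class 1 (default 0.62,
#'   a typical male share in glioma cohorts).
#' @return A `binary_spec` list.
#' @export
binary_spec <- function(n_samples, n_features, n_informative,
                        baseline_rate = 0.3, informative_delta = 0.25,
                        class_share = 0.62) {
  stopifnot(n_informative <= n_features,
            baseline_rate >= 0, baseline_rate <= 1,
            baseline_rate + informative_delta >= 0,
            baseline_rate + informative_delta <= 1,
            class_share > 0, class_share < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 baseline_rate = baseline_rate,
                 informative_delta = informative_delta,
                 class_share = class_share),
            class = "binary_spec")
}

#' Generate a continuous dataset with planted informative features
#'
#' Labels are drawn to match `class_share` exactly (rounded) and shuffled;
#' informative feature positions are sampled; every entry is Gaussian noise
#' (block-correlated within the informative blocks when `n_corr_blocks >
#' 0`) plus `effect_size * noise_sd * label` on informative features.
#' Deterministic for a fixed (spec, seed).
#'
#' @param spec A [continuous_spec()].
#' @param seed RNG seed.
#' @return List with `dataset` (an [omics_dataset()]) and `informative`
#'   (character vector of planted feature names, the ground truth).
#' @export
generate_continuous <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "continuous_spec"))
  n <- spec$n_samples
  p <- spec$n_features
  m <- spec$n_informative
  n1 <- round(n * spec$class_share)
  with_seed(seed, {
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    info <- sort(sample.int(p, m))
    X <- matrix(stats::rnorm(n * p), n, p)
    if (m > 0 && spec$n_corr_blocks > 0 && spec$block_rho > 0) {
      blocks <- split(info, rep_len(seq_len(spec$n_corr_blocks), m))
      for (b in blocks) {
        z <- stats::rnorm(n)
        X[, b] <- sqrt(spec$block_rho) * z +
          sqrt(1 - spec$block_rho) * X[, b, drop = FALSE]
      }
    }
    X <- X * spec$noise_sd
    if (m > 0)
      X[, info] <- X[, info, drop = FALSE] +
        spec$effect_size * spec$noise_sd * labels
    if (spec$lognormal) X <- exp(X)
    fn <- sprintf("F%0*d", nchar(p), seq_len(p))
    ds <- omics_dataset(X, labels, feature_names = fn,
                        sample_ids = sprintf("S%03d", seq_len(n)),
                        value_kind = "continuous")
    list(dataset = ds, informative = fn[info])
  })
}

#' Generate a binary mutation-style dataset
#'
#' @param spec A [binary_spec()].
#' @param seed RNG seed.
#' @return List with `dataset` (binary [omics_dataset()]) and `informative`
#'   (planted feature names).
#' @export
generate_binary <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "binary_spec"))
  n <- spec$n_samples
  p <- spec$n_features
  m <- spec$n_informative
  n1 <- round(n * spec$class_share)
  with_seed(seed, {
    labels <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    info <- sort(sample.int(p, m))
    rate <- matrix(spec$baseline_rate, n, p)
    if (m > 0)
      rate[, info] <- spec$baseline_rate + spec$informative_delta * labels
    X <- matrix(as.numeric(stats::runif(n * p) < rate), n, p)
    fn <- sprintf("G%0*d", nchar(p), seq_len(p))
    ds <- omics_dataset(X, labels, feature_names = fn,
                        sample_ids = sprintf("S%03d", seq_len(n)),
                        value_kind = "binary")
    list(dataset = ds, informative = fn[info])
  })
}
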