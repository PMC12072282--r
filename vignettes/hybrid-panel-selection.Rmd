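---
title: "Hybrid feature selection with rank-based weighting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid feature selection with rank-based weighting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelselect)
```

## The problem

Omics classification studies — serum or tissue proteomics, metabolomics,
mutation panels — routinely face matrices with a few dozen to a few hundred
samples and thousands of features. A classifier fit directly to such a
matrix overfits, and, just as important for biomarker work, it does not
tell the analyst *which* few molecules carry the signal. `panelselect`
addresses the second question: find the smallest feature panel that still
attains the best cross-validated classification accuracy for a binary
phenotype (the motivating application is sex as a biological variable in
glioblastoma cohorts, with serum proteome intensities and tumor mutation
indicators as inputs).

No single selector is reliable here. L1-penalized regression (LASSO) gives
sparse, multivariately justified supports but is unstable under strong
feature correlation; minimum-redundancy–maximum-relevance (mRMR) controls
redundancy explicitly but scores features one at a time. The package
therefore hybridizes the two and lets their *stability across
cross-validation folds* arbitrate.

## The procedure

1. **Stratified k-fold plan** (default k = 5, seed 0). Every fold
   reproduces the cohort's class proportions to within one sample per
   class; fold sizes differ by at most one. The same plan is reused for
   selection and for panel evaluation.
2. **Per-fold selection.** On each fold's *training* split only:
   * `lasso_select`: support of the L1-penalized linear model of the 0/1
     label at penalty `lasso_alpha`, after within-fold z-scoring
     (continuous data).
   * `mrmr_select`: greedy FCQ forward selection of `mrmr_k` features —
     step 1 maximizes the one-way F statistic against the label; later
     steps maximize F divided by the mean absolute Pearson correlation with
     the features already chosen.
3. **Rank-based weight accumulation.** One selector is ranked above the
   other and contributes 2 per fold selection, the other 1; a feature's
   weight is the sum over all folds and both selectors (bounded by 3k = 15
   for five folds). Both static rankings (lasso = 2/mRMR = 1 and the swap)
   are carried through in the default mode; a dynamic mode ranks the two
   selectors per fold by the held-out accuracy of a reference model
   instead.
4. **Threshold sweep.** For every weight threshold `k` from 1 to the
   largest observed weight, the candidate panel is all features with
   weight ≥ k. Panels are nested and shrink as k grows; thresholds with
   identical panels are kept as separate rows, mirroring how such sweep
   tables are conventionally reported.
5. **Six-classifier evaluation.** Every candidate panel is scored by SVM
   (RBF), L2-regularized logistic regression, k-nearest neighbors, random
   forest, AdaBoost, and a soft-voting ensemble of those five, under the
   same fold plan; the score is the unweighted mean of fold accuracies,
   ACC = (TP + TN)/(TP + TN + FP + FN).
6. **Best-panel rule.** The winning cell maximizes mean accuracy; ties go
   to the smallest panel, then the larger threshold, then a fixed model
   order (SVM, LR, KNN, RF, AdaBoost, Voting), then the lasso-first
   ranking. Every tie-break applied is logged.

A worked run:

```{r example, eval = FALSE}
g <- generate_continuous(continuous_spec(100, 1000, 10), seed = 1)
res <- run_pipeline(g$dataset, n_folds = 5, seed = 0,
                    cfg = selector_config(lasso_alpha = 0.01))
res$best
mean(g$informative %in% res$best$feature_names)   # ground-truth recall
```

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `n_folds` | 5 | Stratified CV folds; small-cohort convention. |
| `lasso_alpha` | 1.0 | L1 penalty on the linear model of the 0/1 label. 0.01 is the recommended setting for strongly correlated omics matrices — at 1.0 on z-scored features the support is often empty and the hybrid degenerates to mRMR alone. The simulation studies shipped with the package therefore run at 0.01. |
| `mrmr_k` | 50 | Features returned by mRMR per fold. Directly controls the size of the k = 1 sweep row (the union of all fold selections), so it is surfaced prominently. |
| `scheme` | quotient | FCQ combination (F / mean abs correlation); `difference` subtracts instead. |
| `redundancy_floor` | 1e-6 | Guard against division by a zero mean correlation in the quotient. |
| `random_state` | 0 | Seed fixed before every classifier fit. |
| `holdout_fraction` | 0 | When positive, a stratified share of samples is reserved before any selection and the winning panel is scored on it once. |

Classifier settings are deliberately plain library defaults, recorded in
the run manifest: RBF SVM with cost 1 and Platt probability estimates, KNN
with 5 neighbors, ridge-penalized logistic regression with penalty 1/n
(the conventional unit-strength L2 default), random forest with 100 trees,
AdaBoost with 50 depth-1 stumps (SAMME). There is no hyperparameter
search anywhere in the pipeline, by design: the object under study is the
feature panel, not the classifier.

## Preprocessing and leakage control

Continuous matrices may be log2-transformed up front
(`log2_transform`, pseudocount 1 so zero intensities map to zero).
Within cross-validation, z-scoring is always *fit on the training split*
and applied to the held-out split. Standardized values feed LASSO and the
scale-sensitive classifiers (SVM, KNN, LR); tree ensembles and the mRMR
statistics (both invariant to affine per-feature scaling) see raw values.
Binary mutation matrices are never standardized.

One bias is embedded deliberately: in the default mode the final panels
are evaluated under the *same* fold plan that produced the fold
selections, so features chosen partly on a fold's training data are scored
on folds that overlap that data. This mirrors the convention of the sweep
tables this design reproduces, and it is exactly why the null-calibration
study below shows near-perfect cross-validated accuracy on pure noise. The
`holdout_fraction` option exists as the honest alternative: its samples
never enter selection, and on null data its accuracy collapses to the
majority-class share. Users reporting panel accuracies should prefer the
holdout number.

## The synthetic-data generators

`generate_continuous` plants `n_informative` features carrying a
class-dependent mean shift (`effect_size`, in SD units) in an otherwise
standard-Gaussian matrix; options add within-block correlation among the
planted features (latent-factor construction) and a lognormal transform so
the log2 path is exercised on strictly positive intensities.
`generate_binary` mimics mutation tables: Bernoulli indicators whose rate
differs between classes on informative features. Class imbalance defaults
to 68/32 (continuous) and 62/38 (binary), the male/female proportions
typical of glioblastoma cohorts. Defaults for the benchmark studies —
100 samples, 1000 features, 10 informative at 2 SD, independent features —
were fixed once as a regime where a competent selector should succeed
while leaving room to fail (single-feature F statistics around 20–30,
~400 noise features per informative one).

What the generators do *not* emulate: realistic proteome covariance
(beyond parametric blocks), batch effects, missing values,
heavy-tailed intensity noise, or label noise. Passing the recovery study
therefore shows the machinery is sound, not that any real cohort will
yield a 10-feature panel at 100% accuracy.

## Numerical choices

* The glmnet solver is called with a short decreasing penalty path ending
  at the target, warm-starting coordinate descent deterministically;
  supports come from the exact penalty requested.
* F statistics: constant features get relevance 0 (never chosen before any
  varying feature); a feature with zero within-class variance gets
  relevance `Inf` — a documented consequence is that an exact duplicate of
  such a feature can still be selected, since its quotient score `Inf/1`
  dominates; redundancy only reliably excludes duplicates of features with
  finite relevance.
* All mRMR ties (equal criterion values) break by ascending column index;
  weight-table ties break by feature name; clustergram panels are
  canonicalized by name before clustering so feature order never changes a
  result.
* Every classifier fit runs under a saved-and-restored RNG state seeded
  with `random_state`, making whole-pipeline reruns byte-identical.
* Clustergrams use correlation distance (1 − Pearson) with average
  linkage, the convention of the MATLAB-style clustergram displays this
  reproduces; constant features sit at the maximal distance 2. Row
  z-scores are exact (mean 0, SD 1 within 1e−9) for non-constant features.
* Sweep tables print accuracies as percentages with three decimals;
  heatmap rendering clips z-scores at ±3, the exported matrices are
  unclipped.

## Problem sizes used in the shipped studies

The recovery and null-calibration studies run ten seeds each at
100 × 1000 with five folds and all six classifiers (about 15 s per seed);
oracle-equivalence checks use 100–500 random instances at up to 60 samples
and 12 features, where exhaustive re-evaluation of the greedy criterion is
feasible. These sizes were chosen as the smallest at which each property
is meaningfully exercised.

## Known limitations

* Exactly two base selectors are supported; the weighting scheme (2/1) is
  specific to a two-way ranking.
* Accuracy is the only evaluation metric, matching the sweep-table
  convention the package reproduces; with 68/32 imbalance a majority
  predictor already scores 0.68, so users should read the null-calibration
  discussion above before interpreting absolute accuracies.
* mRMR is the F-statistic/Pearson (FCQ) variant only; mutual-information
  variants would require a discretization policy.
* The dynamic per-fold ranking mode and the static enumeration can pick
  different panels; the static mode is the default because paired
  (lasso = 2/mRMR = 1, lasso = 1/mRMR = 2) sweep blocks are the reporting
  convention this package follows.
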