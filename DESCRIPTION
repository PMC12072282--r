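Package: panelselect
Title: Hybrid Feature Selection and Rank-Based Weighting for Biomarker
    Panel Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers minimal discriminative feature panels in
    high-dimensional omics classification problems (proteomic and
    metabolomic intensity matrices, binary mutation tables). Two base
    selectors, L1-penalized sparse regression (LASSO) and greedy
    minimum-redundancy-maximum-relevance (mRMR, FCQ variant), are run on
    the training split of every stratified cross-validation fold; each
    feature accumulates integer rank weights (2 for the higher-ranked
    selector, 1 for the other) over all folds. Sweeping a weight threshold
    yields nested candidate panels that are scored by six classifiers
    (SVM, logistic regression, k-nearest neighbors, random forest,
    AdaBoost, and a soft-voting ensemble) under the same cross-validation,
    and the smallest panel attaining the highest mean accuracy is
    selected. Includes seeded synthetic-data generators with planted
    informative features, clustergram computation for the chosen panel,
    and reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    e1071,
    randomForest,
    class,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
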