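Package: ctgstack
Title: Stacked Ensemble Classification of Cardiotocography Data with
    Kernel SHAP Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies fetal state from cardiotocography (CTG) feature
    tables with a two-tier stacked ensemble whose meta learner consumes
    base-learner class probabilities mixed with the original features, and
    explains the fitted ensemble with a from-scratch Kernel SHAP estimator
    (coalition enumeration or paired sampling, kernel-weighted constrained
    regression) validated against an exact brute-force Shapley oracle.
    Includes zeros-mean normalization, stratified splits and k-fold
    cross-validation, multi-class imbalanced metrics with class-conditional
    confusion matrices, a synthetic CTG-like data generator, and summary- and
    force-plot data exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    nnet,
    ranger,
    stats,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
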