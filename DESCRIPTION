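Package: misestimatr
Title: Sample-Size Effects on Classifier Accuracy Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how sample size drives misestimation of
    classification accuracy in case/control prediction studies.  Generates
    synthetic cohorts with a known true (Bayes) accuracy and realistic
    class imbalance, runs leakage-free classification pipelines (linear
    and RBF support-vector machines, random forests, PCA and F-test
    feature selection) under leave-one-out cross-validation, and varies
    overall, training and test set sizes with chance-level dummy-prior
    baselines.  Exact binomial and two-class hypergeometric oracles give
    the analytic sampling distribution of accuracy for fixed classifiers
    and chance-level predictors, including exceedance probabilities over
    accuracy thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    jsonlite,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
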