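Package: omicsfusion
Title: Decision-Level Fusion of Paired Omics Classifiers with ReliefF
    Stability Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weighted-average decision-level (late) fusion of per-modality
    probabilistic classifiers for binary cancer-subtype prediction from
    paired expression and copy-number matrices, with exponential
    accuracy-based fusion weights, hard/soft-voting baselines, a ReliefF
    feature-weighting engine, and a stability gene-selection workflow that
    intersects top-ranked gene lists across cross-validation folds, random
    seeds and omics modalities. Includes a synthetic paired-multiomics
    generator with planted class-discriminative genes so the whole
    pipeline is testable end to end without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    e1071,
    nnet,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
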