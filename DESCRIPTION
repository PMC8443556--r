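Package: vsdss
Title: Decision Support for Vestibular Schwannoma Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning decision support on vestibular
    schwannoma (VS) management. Implements two complementary analyses of
    longitudinal checkup records: a static case-based track in which every
    checkup is an independent sample described by audiometric and imaging
    features, and a personalized dynamic track that summarizes each
    patient's wait-and-scan history by temporal metrics (time averages,
    slopes, intercepts, last and total differences). Provides audiogram
    feature derivation, ensemble-consensus feature selection with an
    occurrence/average-rank rule, binary decision trees with explicit
    missing-value routing (including the published reference trees for
    both tracks), classification performance metrics, balanced data
    partitioning, a selector-by-classifier benchmarking grid, and a
    seeded synthetic cohort generator so the full pipeline can be run
    and tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    xgboost,
    glmnet,
    e1071,
    nnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
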