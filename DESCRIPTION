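Package: qolminer
Title: Hierarchical Detection of Health-Related Quality of Life Impacts in
    Patient Forum Messages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A social-media-listening pipeline that detects, in free-text
    patient forum messages, mentions of an impact of disease or treatment on
    health-related quality of life (HRQoL) and attributes each impact to five
    dimensions (physical, psychic, activity-related, relational, financial).
    Provides corpus reading, text normalization and deduplication, dictionary
    driven drug/disease mention matching (exact and approximate),
    lexicon-based feature engineering (lexical-field scores, sentiment
    counts, rule-based French grammar and conjugation counts), SMOTE class
    rebalancing, sequential forward floating feature selection scored by
    cross-validated AUC, grid-search hyperparameter tuning, a two-stage gated
    hierarchical classifier, an evaluation harness (sensitivity, specificity,
    F-measure, ROC/AUC, inter-annotator kappa), and a synthetic labeled
    corpus generator so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    stringi,
    xgboost,
    randomForest,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
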