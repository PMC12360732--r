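Package: phenorisk
Title: Behavioral Risk Prediction from Passively Sensed Mobile Phone Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital-phenotyping pipeline that turns passively collected
    mobile phone event logs (keystroke snapshots, app and website use, GPS
    fixes) into behavioral features and predicts substance-use and sexual-risk
    outcomes against survey-derived labels. Includes keystroke-stream
    deduplication based on Levenshtein similarity, stay-point detection and
    mean-shift place clustering with home inference, lexicon and dictionary
    text featurization, day-averaged text embeddings, leave-one-out
    cross-validated minority-class F1 evaluation of logistic and
    gradient-boosted classifiers, Welch t-test group contrasts, and a
    synthetic-cohort generator with planted, configurable class effects so
    that every stage is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stringi,
    glmnet,
    xgboost,
    geosphere,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
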