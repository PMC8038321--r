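Package: ehglabor
Title: Imminent Labor Prediction from Electrohysterograms in Threatened
    Preterm Labor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting imminent delivery (time to delivery
    of seven days or less) in women with threatened preterm labor from
    30-minute abdominal electrohysterogram (EHG) recordings. Conditions
    the bipolar signal to the 0.1-4 Hz band at 20 Hz, computes 23
    temporal, spectral and nonlinear parameters on 120 s windows with
    50 percent overlap, collapses them per recording by trend-directed
    percentiles, balances the cohort with SMOTE, reduces dimensionality
    with PCA, and designs random forest, extreme learning machine and
    weighted k-nearest-neighbor classifiers over hyperparameter grids
    under F1-score and sensitivity optimization criteria with a
    30-repetition stratified holdout protocol. Includes a synthetic
    cohort generator so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
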