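Package: adrdrisk
Title: Claims-Based Phenotyping and Risk Modelling of Incident Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for identifying incident
    Alzheimer's disease and related dementias (ADRD) from administrative
    claims and modelling future risk. Includes a seeded synthetic claims
    generator with planted case trajectories, a rule-based ADRD case
    phenotyper with confirmation windows and a 60-month incidence washout,
    nested case-control cohort construction with enrollment-duration
    percentile matching, sparse binary feature engineering from a 4th-5th
    pre-index-year window, L1-regularised logistic feature selection
    followed by an unpenalised logistic refit, and prevalence-quantile
    threshold evaluation with sensitivity, specificity, lift and AUC,
    optionally stratified by age.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    glmnet,
    lubridate,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    jsonlite
Config/testthat/edition: 3
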