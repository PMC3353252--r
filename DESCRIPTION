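Package: riskrecal
Title: Transport, Recalibration and Validation of Logistic Risk Prediction
    Models for Incident Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Applies published logistic risk-prediction models for incident
    type 2 diabetes (San Antonio Heart Study, Atherosclerosis Risk in
    Communities, Framingham Offspring) to a new cohort, recalibrates their
    absolute risks from local mean risk-factor levels and the local
    event-free probability, and refits local counterparts by maximum
    likelihood.  Includes an ethnicity-stratified two-step recalibration
    (race terms removed, then within-group recalibration), discrimination
    statistics (AUC with DeLong confidence intervals and paired tests,
    categorical net reclassification improvement), Hosmer-Lemeshow
    calibration tests, fully conditional specification multiple imputation
    with Rubin's-rules pooling for missing follow-up glucose, and a
    synthetic cohort generator emulating a multi-ethnic Asian health-survey
    population so every procedure is testable without access to the
    original data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
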