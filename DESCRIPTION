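Package: graceval
Title: External Validation and Subgroup Recalibration of GRACE-Style Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess and improve the calibration of nomogram-based
    6-month mortality risk scores after acute coronary syndromes within
    patient subgroups, with chronic obstructive pulmonary disease (COPD) as
    the motivating example. Implements table-driven GRACE-style nomogram
    scoring, decile-stratified Mantel-Haenszel risk ratios comparing observed
    mortality between subgroups conditional on predicted risk, logistic
    model respecification with bootstrap internal validation, multiplicative
    subgroup recalibration with risk-band reclassification tables, and
    discrimination and calibration metrics (C-statistic with DeLong paired
    comparison, Hosmer-Lemeshow test, continuous net reclassification
    improvement). A configurable synthetic registry-cohort generator makes
    the whole pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
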