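Package: midpass
Title: Anchor-Based Minimal Important Difference and Patient Acceptable
    Symptom State Estimation for Outcome Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the minimal important difference (MID) and the
    patient acceptable symptom state (PASS) of bounded patient-reported
    outcome instruments against an ordinal satisfaction anchor collected
    longitudinally. Implements four anchor-based MID estimators (ROC
    closest-to-top-left cut-point, mean difference of change, mean change,
    and the predictive-modelling method based on logistic regression), two
    PASS estimators (ROC and the 75th/25th percentile method among
    satisfied participants), Spearman anchor-credibility screening with
    bootstrap confidence intervals, and a calibrated synthetic-cohort
    generator for longitudinal anchor-outcome data with analytically known
    targets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
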