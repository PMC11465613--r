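Package: t2dval
Title: External Validation of Non-Invasive Type 2 Diabetes Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating non-invasive type 2 diabetes
    risk scores (ADRS, Simplified FINDRISC, ADA, IRS and user-supplied
    models) against screen-detected diabetes defined by fasting plasma
    glucose or HbA1c. Implements cohort assembly with first-diagnosis visit
    selection and model-specific complete-case filtering, declarative
    score specifications, discrimination statistics (C-statistic with
    DeLong confidence intervals, ROC curves, Youden and top-left optimal
    thresholds, subgroup comparison), calibration statistics
    (expected/observed ratio with Poisson intervals, Brier score, Yates
    slope, Hosmer-Lemeshow test, calibration bins) and intercept-update
    recalibration, plus a seeded synthetic longitudinal cohort generator
    for end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    readr,
    ggplot2,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
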