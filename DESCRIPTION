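Package: rxfill
Title: Linking Prescribing and Pharmacy Dispensing Records to Study Medication Fill Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking electronic health record prescribing events to
    pharmacy dispensing records across the RxNorm (RxCUI) and National Drug
    Code (NDC) ontologies, and for the downstream analysis of primary
    medication nonadherence: new-user cohort construction with a washout
    period, standardized-mean-difference covariate balance tables,
    cross-validated penalized-logistic propensity models with inverse
    probability weighting, and marginal and weighted Cox hazard ratios for
    time to follow-up. Includes a synthetic electronic-health-record data
    generator with known ground truth so the full pipeline is testable
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
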