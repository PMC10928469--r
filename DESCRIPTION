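Package: cvdclaims
Title: Claims-Based Identification and Validation of First and Recurrent
    Cardiovascular Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies first and recurrent acute myocardial infarction (AMI)
    and stroke events from health-insurance claims. Consecutive claims are
    grouped into hospitalization episodes using a 28-day first-date gap and a
    3-day discharge-to-admission interval rule, episodes are classified with
    position-aware ICD-10 diagnosis-code rules supplemented by procedure
    evidence and in-episode death, and per-patient episodes are sequenced into
    first and recurrent event calls. Includes stratified and pooled positive
    predictive value (PPV) estimation with binomial confidence intervals for
    chart-review validation, and a synthetic claims generator with known
    ground truth that emulates 30-day billing splits, complication
    readmissions, and carried-over diagnosis codes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
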