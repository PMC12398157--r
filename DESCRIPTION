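Package: ppcvd
Title: Development and Validation of Postpartum Cardiovascular Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for developing, updating and validating
    10-year cardiovascular disease risk prediction models in postpartum
    women. Provides a synthetic electronic-health-record cohort generator
    with a proportional-hazards event model, a QRISK-style risk equation
    engine with fractional-polynomial terms, Cox model development with
    LASSO selection and forced covariates, Breslow baseline estimation and
    offset recalibration, and a full validation suite: Harrell's and Uno's
    concordance, Royston's D, pseudo-value calibration (intercept, slope,
    binned curves), observed/expected ratios, decision-curve net benefit,
    and bootstrap optimism correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
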