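Package: das2c
Title: Derivation and Validation of a Two-Component Imaging-Weighted DAS28
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive and validate a two-component disease activity
    score (2C-DAS28CRP) for early rheumatoid arthritis, re-weighted against
    ultrasound-detected synovitis. Implements joint-level grey-scale/power
    Doppler combination into a scalar GSPD outcome, conventional DAS28/SDAI/
    CDAI formulas, robust regression on order statistics for left-censored
    CRP, multiple imputation by chained equations with predictive mean
    matching and Rubin pooling, random-intercept linear models compared by
    patient-clustered 20-fold cross-validated R-squared and test
    log-likelihood, observation-weighted coefficient-ratio score derivation,
    and longitudinal radiographic validation via generalized estimating
    equations (QIC) and random-intercept models of Larsen damage scores.
    Includes synthetic-cohort generators emulating the development and
    validation data structures for end-to-end and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
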