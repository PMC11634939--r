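Package: cmlrisk
Title: Constrained Maximum Likelihood for Well-Calibrated Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits logistic risk models that add new predictors to an
    established, well-calibrated base model while enforcing calibration in a
    target population. Maximum likelihood estimation is carried out under
    interval-level constraints that keep the fitted model's average predicted
    risk close to the base model's within risk strata of the target
    population, with the conditional distribution of the new predictor
    modelled as a truncated log-normal. Provides active-set (KKT) asymptotic
    standard errors via a projected sandwich covariance, calibration
    diagnostics (expected cases per 100,000, decile calibration tables), and
    a synthetic-data engine for covariate-shift simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
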