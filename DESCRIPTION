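Package: saeprev
Title: Small Area Estimation of District Prevalence from Complex Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design-weighted direct estimation, Fay-Herriot area-level
    modelling, and unit-level logistic mixed modelling with empirical best
    prediction for small-area (district-level) prevalence from two-stage
    cluster surveys. Includes Taylor-linearization standard errors for the
    Hajek ratio estimator, REML/ML variance-component estimation with
    Prasad-Rao mean squared error, parametric-bootstrap MSE for the
    empirical best predictor, precision and consistency diagnostics
    (coefficient of variation, bias regression, MSE-ratio precision gain),
    and a synthetic two-stage cluster survey generator for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    lme4,
    pracma,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
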