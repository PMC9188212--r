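Package: aftfirth
Title: Firth-Penalized Accelerated Failure Time Models for Small or
    Heavily Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood and Firth-penalized estimation for
    accelerated failure time (AFT) regression in the log-location-scale
    family (Weibull, log-normal, log-logistic).  The Firth penalty (half
    the log-determinant of the observed information, i.e. the log of the
    Jeffreys invariant prior) removes the leading-order bias of the
    maximum likelihood estimator and guarantees finite coefficient
    estimates under separation or monotone likelihood, which arises with
    small samples, heavy censoring, or strong binary covariates.  Includes
    a post-hoc re-estimation of the intercept and scale with the penalized
    slopes held fixed as an offset (so survival predictions are not
    over-shrunk), survival-probability and survival-time-quantile
    prediction, a separation / near-to-separation diagnostic for censored
    data, and a Monte Carlo study engine reporting bias, mean squared
    error, analytic and simulation standard errors, and Wald
    confidence-interval width.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
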