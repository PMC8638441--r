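Package: hurdletraj
Title: Latent-Class Heteroskedastic Hurdle Trajectory Models for Daily Therapy Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent-class trajectory models to daily therapy-adherence
    time series in which each day is a two-part (hurdle) outcome: a Bernoulli
    attempt process and, conditional on an attempt, a zero-truncated normal
    time on therapy. Each latent class describes the attempt probability
    (logit link), the conditional mean usage (identity link, with a patient
    random intercept marginalized by adaptive Gauss-Hermite quadrature), and
    the day-to-day variability (log link) as quadratic functions of time.
    Mixtures are estimated by weighted EM over per-patient marginal
    likelihoods, with deviance-based stopping, random restarts, information
    criteria, relative entropy, randomized quantile residual diagnostics, a
    synthetic-cohort simulator, and three-step post-hoc group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
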