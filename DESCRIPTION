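Package: cmpbar
Title: Conway-Maxwell-Poisson-Binomial AR(1) Models for Bounded Count Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bounded count time series on {0,...,n} whose units are
    exchangeable and dependent. Implements the Conway-Maxwell-Poisson-binomial
    (CMPB) distribution (pmf, moments, binomial index of dispersion, exact
    sampler), the exchangeable CMPB thinning operator, and the CMPBAR(1)
    autoregression built from two independent CMPB thinnings. Provides the
    exact finite-state transition structure and stationary distribution,
    conditional maximum likelihood estimation with Hessian and sandwich
    standard errors, the classical binomial AR(1) competitor fit, AIC/BIC model
    comparison, Pearson residual and probability-integral-transform
    diagnostics, and a Monte-Carlo simulation-study driver. Results are
    returned as tibbles with broom-style tidy() and glance() methods and
    ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    numDeriv,
    parallel,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
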