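Package: lcsmr
Title: Specify, Simulate, Fit and Visualise Latent Change Score Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for univariate and bivariate latent change score models
    (LCSMs) for longitudinal data in wide format. Declarative model options
    (constant, piecewise and linear change factors, proportional change,
    autoregression of change scores, and eight cross-construct coupling
    options) are compiled into RAM-style structural matrices and
    human-readable lavaan-dialect model syntax. A self-contained estimation
    engine computes model-implied moments, evaluates the full-information
    maximum likelihood under missing data, fits models by quasi-Newton
    optimisation, and reports standard errors and fit statistics
    (chi-square, AIC, BIC, CFI, RMSEA, SRMR). Companion functions simulate
    data from any specification with MCAR missingness, extract tidy tables
    of fit statistics and parameter estimates, plot individual trajectories
    and simplified path diagrams, and expose the whole workflow on the
    command line.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
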