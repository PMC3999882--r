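Package: propdiffsim
Title: Monte Carlo Comparison of Regression Estimators for Proportion
    Differences on the Unit Interval
Version: 0.1.0
Authors@R:
    person("propdiffsim", "maintainers", email = "maintainers@propdiffsim.org",
           role = c("aut", "cre"))
Description: Simulation framework for comparing estimators of the average
    proportion difference in a two-sample design when the response lives on
    the open unit interval (0,1). Implements seeded beta and discrete
    multinomial data generators in the mean-dispersion parameterization,
    four likelihood-based fitters (ordinary least squares, constant-dispersion
    beta regression, variable-dispersion beta regression with a log-linked
    dispersion sub-model, and fractional logit regression with a robust
    sandwich covariance), delta-method inference on the mean difference, and
    a replication harness reporting bias, variance, rejection rates and their
    Monte Carlo errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
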