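Package: fertgp
Title: Semi-Parametric Fertility Modelling with Gamma Age-Patterns and
    Gaussian Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits age-specific fertility schedules in which the fertility
    rate over age follows a Gamma-density curve whose shape and scale
    parameters vary smoothly over socio-economic status and calendar year
    through Gaussian process regression with a squared-exponential kernel.
    Provides quantile binning of woman-year census records into empirical
    rate tables, per-slice maximum-likelihood Gamma fits, marginal-likelihood
    (MAP) kernel hyperparameter estimation with a smoothing prior on the
    socio-economic-status lengthscale, model selection by ten-fold
    cross-validated Brier score and Kolmogorov-Smirnov goodness of fit with
    Bonferroni correction, parametric bootstrap confidence bands, stratified
    refits, and a synthetic woman-year data generator with known ground
    truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
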