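Package: carpanel
Title: Bayesian Spatio-Temporal CAR Models for Areal Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian hierarchical modelling of rectangular area-by-year
    panels (e.g. district-level crop yield rates against climate covariates)
    with structured spatio-temporal random effects. Implements four model
    families -- an independent-error Gaussian GLM and spatio-temporal
    linear-trend, ANOVA and first-order autoregressive models -- with
    Leroux-form conditional autoregressive (CAR) priors on spatial and
    temporal effects, fitted by a Gibbs/Metropolis-within-Gibbs sampler.
    Provides model choice criteria (DIC, WAIC, log marginal predictive
    likelihood), validation statistics (RMSE, MAE, Gaussian CRPS, predictive
    interval coverage), residual aggregations, a synthetic-panel generator
    with known ground truth, and an end-to-end pipeline with plain-text
    input/output formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
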