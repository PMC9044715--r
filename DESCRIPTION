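Package: circmanova
Title: MANOVA for Circular Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests and models for angular (circular) response data via the
    multivariate linear model on the (cosine, sine) embedding. The Pillai
    trace test of the model intercept serves as a test of circular
    uniformity, while grouping factors, linear covariates and their
    interactions are tested in the same model with sequential (Type-I)
    sums of squares and cross-products. Includes Monte-Carlo calibration
    of p-values against the uniform null, the Rayleigh and Hermans-Rasson
    reference tests, samplers for von Mises, wrapped skew-normal and
    circular mixture distributions, a simulation harness for type-I error
    and power studies, and eta-squared/AIC based model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
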