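Package: greyshap
Title: Combined Grey Verhulst and Regression Forecasting with Shapley Weights
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a grey Verhulst (logistic saturation) trend model and a
    six-covariate multiple linear regression to short annual mortality
    series, apportions the two models' comprehensive relative errors by
    Shapley value, and converts the shares into convex combination weights
    for a combined point forecaster. Includes residual testing (per-year
    relative errors and the comprehensive mean error), seeded synthetic
    generators for both model classes, plain-text readers and writers,
    bundled Chinese road-traffic fatality data (2002-2013) with covariates,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
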