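Package: fieldspat
Title: Spatial Regression and Evaluation for Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regression on spatially autocorrelated field-trial
    data. Simulates field layouts with linear gradients, edge effects and
    Gaussian-decay spatial correlation; fits ordinary and generalized least
    squares with a Gaussian-decay covariance model estimated by (restricted)
    maximum likelihood; fits a GLS elastic net that alternates between
    whitened penalized regression and covariance re-estimation; and provides
    spatially aware evaluation: blocked (k-means) cross-validation,
    mean-centered R-squared, expectation-adjusted Moran's I, feature-selection
    metrics including the proportion of spatially structured features among
    discoveries, and a Monte-Carlo benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    nlme,
    optparse,
    readr,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
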