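Package: cropfragility
Title: Conditional Extreme Value Modelling of Crop-Yield Losses Under
    Weather Extremes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates the probability of extreme crop-yield losses
    conditional on extreme weather from pooled country-year panels.
    Implements semi-parametric marginal models (empirical body plus a
    generalized Pareto tail), transformation to standard Laplace margins,
    the conditional multivariate extremes dependence model of Heffernan
    and Tawn with the joint parameter constraints of Keef,
    Papastathopoulos and Tawn, Monte-Carlo extrapolation of conditional
    loss probabilities with semi-parametric bootstrap confidence
    intervals, and region-by-crop fragility summaries.  A synthetic panel
    generator with known tail-dependence structure (Gaussian and logistic
    copulas, exact conditional-model forms) and brute-force Monte-Carlo
    oracles support validation of every stage.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
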