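Package: geosfa
Title: Bayesian Geoadditive Stochastic Frontier Analysis for Hospital
    Quality-of-Care Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian stochastic frontier models in which technical
    inefficiency is scaled by observable determinants and by structured
    (Gaussian Markov random field) plus unstructured regional random
    effects.  Designed for hospital production frontiers that treat
    realized quality (deaths, readmissions) and staffing as inputs and
    risk-adjusted patient volume as output.  Includes panel preparation
    (risk-adjusted output construction, zero-input encoding, centering),
    an MCMC engine with DIC/WAIC model comparison, a post-estimation
    layer (technical efficiency, variance ratio, slack resources,
    marginal effects, policy scenarios), a matching plus
    difference-in-differences robustness check, and a synthetic
    hospital-panel generator with known ground truth.
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
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
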