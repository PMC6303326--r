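Package: forestbpr
Title: Biodiversity-Productivity Relationships of Forest Plots Across Climate Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the biodiversity-productivity relationship
    (BPR) of forest inventory plots across climate space. Provides a synthetic
    generator of FIA-like plot tables with known structural parameters,
    decile binning of plots in mean-annual-temperature by annual-precipitation
    space, per-unit Gaussian GLM classification of the BPR form (linear vs.
    hump-shaped, selected by AIC), a logistic decision boundary between BPR
    types in climate space, and a hierarchical Bayesian structural model
    (five sub-models, 18 slope coefficients, ecoregion random intercepts,
    fitted by MCMC via JAGS) with posterior-based BPR classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
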