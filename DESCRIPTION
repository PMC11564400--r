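Package: twinpath
Title: Direction-of-Causality and Cross-Lagged Twin Models for Paired Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biometric structural-equation modelling for twin-pair data aimed at
    testing the direction of causality between two developmental traits. Implements
    ACE variance decomposition on observed scores or latent factors, bivariate
    Cholesky and Direction-of-Causation (DoC) models, the Mendelian-randomization
    DoC model with a polygenic-score instrument, and cross-lagged twin models
    extended with cross-time genetic and shared-environment confound correlations.
    Models are expressed in reticular (RAM) form and fitted by full-information
    maximum likelihood that accommodates missing data; includes local
    identification checking by Jacobian rank, chi-square difference and AIC model
    comparison, Wald-based pruning of non-significant paths, Wright path-tracing
    (trek) decomposition of model-implied cross covariances, and a synthetic
    twin-cohort generator that emulates the statistical structure of a
    two-timepoint twin study with polygenic scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
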