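Package: lopitdyn
Title: Dynamic Spatial and Temporal Proteomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dynamic subcellular proteomics experiments that pair
    hyperLOPIT-style density-gradient fractionation profiles across two
    conditions with multiplexed whole-proteome time courses. Provides
    PSM-level quality filtering, missing-value imputation (k-nearest
    neighbours for values missing at random, left-censored minima for
    intensity-dependent missingness), sum and generalised-log normalisation,
    a semi-supervised T-augmented Gaussian mixture classifier fitted by
    collapsed Gibbs sampling with an explicit multivariate-t outlier
    component, detection and typing of protein translocation events from
    posterior allocation profiles, paired moderated t-tests with
    empirical-Bayes variance shrinkage, Dirichlet-process mixtures of
    Gaussian-process regression models for temporal clustering with posterior
    similarity summarisation, Fisher's exact and hypergeometric association
    tests, and seeded synthetic-data generators that emulate the statistical
    structure of such experiments for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
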