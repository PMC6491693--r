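Package: cfascale
Title: Scaling Latent Variable Variances in Confirmatory Factor Analysis
    While Preserving the Model-Implied Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for rescaling the variance parameters of latent variables
    in confirmatory factor analysis (CFA) without changing the model-implied
    covariance matrix. Implements the marker-variable, reference-group,
    effect-coding and squared-loadings (criterion-based) scaling methods as
    scalar multiplications of the loading and latent-covariance matrices,
    a constancy checker for the true part Lambda Phi Lambda', comparison
    scaling (criterion number 1) that turns latent variances into
    explained-variance contributions comparable across factors, a minimal
    maximum-likelihood CFA fitter supporting each identification method at
    estimation time, and a seeded synthetic-data generator for population
    and sampled covariance studies.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
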