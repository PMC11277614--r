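Package: gmltmd
Title: Bayesian Multicomponent Latent Trait Models for Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation and checking of noncompensatory multicomponent
    item response models for binary data decomposed by a feature (Q) matrix:
    the linear logistic test model (LLTM), a constrained two-parameter
    logistic model, the multicomponent latent trait model for diagnosis
    (MLTM-D), and its three-parameter generalization (GMLTM-D) with
    group-shared discriminations and item guessing. Includes an adaptive
    Metropolis-within-Gibbs sampler, convergence diagnostics, prior and
    posterior predictive checks, SRMR and WAIC model comparison, a seeded
    response simulator with a parameter-recovery harness, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    coda,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
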