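Package: msvae
Title: Disentangled Variational Autoencoders for Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for learning and auditing disentangled latent
    representations of tandem mass (MS/MS) spectra. Provides readers and
    writers for MSP/MGF spectral libraries, a sparse interleaved
    (m/z, intensity) vector representation of spectra, BetaVAE and
    JointVAE generative models with optional jointly trained downstream
    factor predictors, reconstruction metrics with an
    average-reconstruction baseline, ranked spectral-similarity scoring,
    latent-space traversal and spherical interpolation, supervised
    disentanglement scores (BetaVAE, FactorVAE, Mutual Information Gap),
    permutation feature importance, and a two-step factor/latent
    pairwise-correlation analysis with greedy factor-to-latent
    assignment. A seeded synthetic spectrum generator with known factors
    of variation makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
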