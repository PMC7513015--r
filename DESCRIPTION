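Package: rmme
Title: Reliable Moment Maximum Entropy Models for Neural Population Spike Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits maximum entropy (log-linear) models with adaptively selected
    pairwise and higher-order interactions to binary population spike rasters.
    Interaction features are chosen by thresholding uncentered sample moments,
    which yields downward-closed feature sets by the moment hierarchy; the
    resulting Reliable Moment model is fitted by Minimum Probability Flow
    learning or exact maximum likelihood, and normalized exactly (brute force),
    by a Good-Turing coverage estimate, or from the silent-state frequency of
    Gibbs samples. Includes the Reliable Interaction baseline (pattern-frequency
    feature selection with algebraic parameter solving), a Gibbs sampler for
    arbitrary-order models, ground-truth simulators (random pairwise maximum
    entropy populations and Dichotomized Gaussian populations with cortical-like
    rates and correlations), and evaluation utilities for comparing model and
    empirical pattern frequencies on held-out data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    mvtnorm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
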