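Package: sbel
Title: Spatial Bayesian Empirical Likelihood Models for Small-Area Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-parametric Bayesian small-area estimation combining an
    empirical likelihood for the data with conditional autoregressive
    spatial priors (independent Gaussian, intrinsic CAR, Leroux, and the
    generalised Moran eigenvector basis). Includes a random-walk
    Metropolis-Hastings sampler with empirical-likelihood feasibility
    gating and pilot-chain tuning, grid search over the Leroux mixing
    parameter, stable WAIC model selection, Gelman-Rubin diagnostics, a
    lattice disease-mapping scenario simulator, and readers for areal CSV
    tables and GAL spatial-weights files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
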