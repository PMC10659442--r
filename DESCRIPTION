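Package: snapBDD
Title: Inference of Birth-Death-Diffusion Rates from Particle Snapshots
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers nondimensional birth and death rates of particles
    undergoing birth at a point source, Brownian diffusion, and
    first-order decay inside absorbing one-dimensional cell domains,
    from fixed-time snapshots of particle positions such as those
    produced by single-molecule FISH imaging. Snapshot data are modelled
    as an inhomogeneous spatial Poisson point process whose intensity
    solves a birth-death-diffusion boundary-value problem with a known
    closed form. The package provides the exact point-process likelihood
    and its binned counterpart, Fisher information and D-optimality
    analysis (including averaging over cell-to-cell geometric
    heterogeneity), a Gibbs-within-Metropolis posterior sampler with
    Gamma conjugacy in the birth rate, highest-density posterior regions,
    and both trajectory-level and direct Poisson simulators for
    generating synthetic snapshot data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
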