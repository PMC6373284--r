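Package: veinsim
Title: Hybrid Multiscale Simulation of Vein-Graft Vascular Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional hybrid simulator of vein-graft adaptation after
    bypass surgery. Couples a steady mechanical model of lumen blood flow,
    wall shear stress, thick-cylinder strain energy and growth-factor
    diffusion to a stochastic agent-based model of smooth-muscle-cell (SMC)
    division, apoptosis, migration and extracellular-matrix (ECM) turnover,
    with tissue reorganisation computed by an immersed-boundary (Peskin)
    method carrying mass sources and sinks, off-lattice multi-potential cell
    motility, and an energy-minimising inward/outward remodeling adjustment.
    Includes a reduced zero-dimensional dynamical system and a seeded genetic
    algorithm for cross-validating the hybrid model's lumen-area dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    readr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
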