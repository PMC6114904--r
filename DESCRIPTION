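Package: catchbond
Title: Structure-Based Kinetics of Protein Catch Bonds Under Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a structure-based model for catch bonding in the
    cadherin-catenin-actin adhesion complex: a two-basin energy landscape
    over bond extension and the alpha-catenin M2-M3 inter-domain angle, its
    reduction to a four-rate two-state kinetic scheme with an absorbing
    rupture state, analytical mean bond lifetimes and double-exponential
    survival probabilities under constant force, and maximum-likelihood
    estimation of the landscape parameters from single-molecule
    force-spectroscopy lifetime data. Includes two independent numerical
    oracles (a finite-volume mean-first-passage-time solver for the
    Smoluchowski equation and an overdamped Brownian-dynamics simulator), a
    Gillespie generator for experiment-like synthetic lifetime datasets, and
    tidy accessors and plots for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
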