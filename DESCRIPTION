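Package: difftrace
Title: Cut-Based Free Energy Profiles and Reaction Coordinate Optimization
    for Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether molecular dynamics projected on a putative
    reaction coordinate is diffusive or sub-diffusive, using cut-based
    free energy profiles (transition-count partition functions), the
    natural-coordinate transform, coordinate-dependent anomalous-diffusion
    exponents, and Kramers mean-first-passage-time integration.  Constructs
    near-optimal one-dimensional reaction coordinates from multi-atom
    trajectories by stochastic coordinate ascent on the mean first passage
    time, over contact-based and distance-combination coordinate families.
    Includes seeded synthetic generators (overdamped Langevin double well,
    two-state atomistic toy trajectories with correlated noise, exact
    fractional Brownian motion) so every stage is testable without external
    trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    bio3d,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
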