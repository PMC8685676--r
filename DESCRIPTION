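Package: spinchoice
Title: Embodied Spatial Decision-Making with Direction-Tuned Spin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of spatial decision-making on the move.
    Implements a minimal neural decision model in which a network of binary
    spins, each tuned to the egocentric direction of one spatial target,
    evolves by Metropolis dynamics under a direction-dependent interaction
    kernel; the consensus vector of active spins steers a moving agent, and
    the recursive interplay between motion and the resulting time-varying
    geometry produces sequential binary bifurcations in the trajectory.
    Includes numerical phase-diagram characterization of the
    compromise-to-decision transition (order parameter, susceptibility,
    hysteresis), trajectory statistics (time-normalized density maps,
    piecewise critical-point fits, y-swap randomization tests, track
    classification, moving-frame marginals), a zonal collective-motion
    analogue with goal-weight feedback, geometry presets, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
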