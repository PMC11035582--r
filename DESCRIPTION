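Package: alleeSensor
Title: Allee-Effect Distributed Detection for Microbial Whole-Cell Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for an Allee-effect-based
    distributed detection algorithm in engineered microbial populations.
    Cells hold a binary vote (low/high state) about the presence of a rare
    analyte; a quorum-sensing-driven positive feedback with Hill kinetics
    creates bistable population dynamics with a sharp detection threshold.
    The package integrates the population ODE under constant or time-varying
    analyte profiles, finds and classifies equilibria, locates the critical
    rare-event detection rate at the saddle-node bifurcation by binary
    search, sweeps it over rate-parameter grids, compares the algorithm
    against set-reset, broadcasting and distributed-amplification
    alternatives, and tests false-positive robustness against stochastic
    birth-death noise fed into a hybrid stochastic-deterministic simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
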