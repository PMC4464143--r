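Package: protocontagion
Title: Emotional Contagion, Order Parameters, and Proto-Community Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based and mean-field tools for studying how shared
    emotional states spread through a population and stabilize into
    proto-communities. Implements a bi-state (positive/negative emotional
    attractor) population substrate with an order parameter in [-1, 1], a
    generalized dose-memory-threshold contagion engine with
    susceptible/infected/removed compartments, the analytic mean-field map
    for the r = rho = 1 case with fixed-point and regime analysis, and the
    cusp-catastrophe model of the order parameter under two control
    parameters, including pitchfork/fold bifurcation structure and
    hysteresis sweeps. Includes seeded scenario fixtures, membership
    turnover experiments with persistence scoring, phase-transition
    detection, plain-text configuration files, and a command-line
    interface emitting CSV time series and JSON summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
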