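Package: growthreg
Title: Verhulst Growth Models, Coexistence Regimes, and Coupling-Based
    Population Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of logistic (Verhulst) population
    growth in three settings: a single uncoupled species, a species coupled
    to an exogenous signal (e.g. harvesting pressure), and two coexisting
    species coupled through signed interaction parameters.  Provides
    closed-form dynamic properties (equilibria, final values, inflection
    points, transitory and inflection times), classification of the six
    ecological interaction regimes (neutralism, commensalism, amensalism,
    mutualism, competition, predation) with feasibility and stability
    flags, feedback control laws that regulate a population to a desired
    final value by manipulating its coupling parameter, and a fixed-step
    Runge-Kutta scenario simulator with seasonal open-loop and closed-loop
    harvesting schedules.  Ships built-in fishery scenarios and a
    command-line interface producing CSV trajectories and JSON property
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
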