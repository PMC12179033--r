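Package: mlsconflict
Title: Multilevel Selection with Pairwise Group-Level Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a hyperbolic PDE model of
    multilevel selection in which a population of groups evolves under
    within-group replicator dynamics and pairwise group-level conflict.
    Groups are characterised by their fraction of cooperators in a
    two-player, two-strategy social dilemma; between-group competition is
    governed by a pairwise victory-probability kernel and a relative
    conflict strength lambda. Provides the game-theoretic rate functions,
    a family of victory kernels (fraction-based, local update, Fermi,
    normalized difference, Tullock contest, additively separable), a
    conservative first-order upwind finite-volume solver, a measure-valued
    particle solver based on the characteristic flow and Picard iteration
    on the implicit representation formula, analytic threshold and
    steady-state predictions, Hoelder tail-exponent diagnostics, scenario
    presets, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
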