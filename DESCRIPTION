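Package: explife
Title: Optimal Lifetime Exploration-Exploitation Strategies by Optimal Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Solves a two-state life-history model of the
    exploration-exploitation trade-off. A subject allocates a
    learning-investment rate u(t) over its lifespan to maximize terminal
    energy, where energy intake saturates with accumulated knowledge and
    knowledge decays over time. The optimal strategy is computed by direct
    Hermite-Simpson collocation with an augmented-Lagrangian solver, verified
    against a backward dynamic-programming oracle and Pontryagin
    necessary-condition diagnostics, and segmented into knowledge phases
    (establishment, accumulation, maintenance, exploitation). Includes
    forward simulation of arbitrary strategies, parameter sweeps over
    life-history and environmental parameters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
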