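Package: fescycle
Title: Reinforcement-Learning Adaptation of Stimulation Patterns for FES-Cycling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Closed-loop control toolkit for functional electrical stimulation
    (FES) cycling. A decayed-epsilon-greedy reinforcement-learning agent adapts
    each stimulation channel's baseline pulse amplitude and width under a
    charge-versus-cadence-error reward, while a proportional-integral controller
    modulates pulse amplitude to track a reference pedaling cadence. A synthetic
    crank, muscle-recruitment and fatigue environment lets the full loop run and
    be tested without a stimulator or a rider. Includes session orchestration
    with 10-Hz logging, scenario presets, and metrics for injected electrical
    charge, accumulated reward and cadence error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
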