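Package: atpsim
Title: Affective Two-Process Simulation of Partial Reinforcement Extinction Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based simulator of an affective-associative two-process
    (ATP) model of operant discrimination learning. A dual-dimension temporal
    difference critic learns reward-magnitude and reward-omission value over a
    complete-serial-compound stimulus representation; a neural-dynamic actor
    turns the two value dimensions into mutually inhibitory reward and omission
    expectancies that, together with a direct stimulus-response route, mediate
    response choice. Ships the two within-subjects discrimination protocols
    (continuous versus partial reinforcement; high versus low reward density)
    used to study partial reinforcement extinction effects (PREE) and their
    reversal (RPREE), plus lesion variants, learning-rate sensitivity sweeps,
    and the block-proportion, PREE-index, mixed-ANOVA and paired-t analyses
    used to summarise them.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
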