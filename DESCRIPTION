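Package: polyrepsim
Title: Stochastic Simulation of Early Replication in Polytene Chromosome
    Band/Interband Fragments
Version: 0.1.0
Authors@R:
    person("polyrepsim", "developers", email = "polyrepsim@example.org",
           role = c("aut", "cre"))
Description: Event-driven stochastic simulation of DNA replication
    initiation and bidirectional fork progression in a multi-chromatid
    (polytene) chromosome fragment. Models band/interband geometry with
    compaction-dependent axial fork speed, per-chromatid random origin
    choice inside interbands, temporal initiation scenarios (synchronous
    or uniform activation windows), snapshot dot patterns and axial
    density profiles, a synthetic microscope-level observation layer
    (detection dropout, localization jitter), and a scenario-recovery
    classifier that infers the initiation-rate regime from observed dot
    density patterns. Includes a command-line pipeline with seeded,
    byte-reproducible outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
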