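Package: insulitisSim
Title: Agent-Based Simulation of CD8+ T Cell / Beta Cell Interactions in Insulitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded, configurable lattice simulator of the autoimmune attack on
    pancreatic islets in NOD-mouse insulitis. Simulates naive, effector and memory
    CD8+ T cells on a two-dimensional tissue grid with persistent random-walk
    motility, basement-membrane erosion, conjugate-based killing of insulin-producing
    Beta cells, generation-tracked proliferation with memory differentiation, and
    optional Beta-cell regeneration. Includes an ensemble runner, quartile summary
    statistics, half-loss-day and inflammation-window metrics, scenario presets, and
    deterministic micro-fixtures with statistical oracles for rule-level validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
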