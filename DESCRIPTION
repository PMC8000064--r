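Package: hubscreen
Title: Hub-Gene Discovery from Expression, Interaction and Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-usable pipeline for hub-gene discovery in
    treatment-resistance transcriptomics: differential-expression calling
    across serial xenograft generations, partition of consistently
    differential genes, confidence-filtered protein-protein interaction
    networks, a hybrid centrality hub score (degree + closeness +
    betweenness + mean neighbour degree), MCODE-style dense-module
    detection, hypergeometric over-representation analysis of gene sets,
    and a Kaplan-Meier / log-rank / proportional-hazards survival screen.
    Ships seeded synthetic-data generators with planted ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
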