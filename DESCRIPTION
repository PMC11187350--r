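Package: herbnetsep
Title: Herb-Symptom Cohort Statistics and Interactome Network Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis linking medicinal-herb usage to symptom
    relief in an inpatient cohort and to molecular mechanism through
    protein-protein interactome proximity. Provides readers for edge-list
    interactomes, GMT gene sets and structured cohort tables; 2x2
    contingency and symptom-improvement statistics; the closest-distance
    network metric d(X,Y) and the network separation score S_AB between a
    herb target set and symptom gene sets; seeded synthetic generators for
    interactomes with planted proximal or distal gene modules and for
    Bernoulli symptom-relief cohorts, including a deterministic replay
    fixture of published cohort marginals; and an end-to-end pipeline with
    a reproducible report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
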