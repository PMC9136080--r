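Package: netpharm
Title: Quantitative Network Pharmacology for Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative network-pharmacology pipeline for dissecting
    multi-component herbal formulas. Builds a weighted disease gene network
    from protein-protein interactions and literature evidence counts, extracts
    a functional response space (FRS) of effective proteins with a
    node-importance measure combining shortest-path betweenness with an
    inverse-squared-distance proximity term, selects a key functional
    components group (KFCG) by greedy contribution-ratio coverage, scores
    components on the tripartite component-target-pathway network with a
    potential effect score (PES), screens components by ADME thresholds
    (oral bioavailability, Caco-2 permeability, drug-likeness), runs
    hypergeometric over-representation analysis with coverage validation
    metrics, and estimates brain concentrations of components from formula
    doses by linear cross-species scaling. Ships seeded synthetic-data
    generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
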