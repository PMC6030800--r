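Package: herbnet
Title: Association Rule Mining and Modular Network Analysis of Herbal
    Prescription Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining herb co-prescription structure from
    transaction tables of traditional herbal formulas. Implements
    level-wise apriori itemset counting with support/confidence/lift
    rule scoring for two- and three-herb combinations, weighted
    co-occurrence network construction with Louvain modularity
    maximisation at a configurable resolution, and a module-label
    permutation test for meridian-tropism enrichment with
    Benjamini-Hochberg false discovery rate control. Includes a
    seeded synthetic-corpus generator with planted co-prescription
    modules and planted meridian enrichment for validation and
    calibration, a fixture builder that realises exact marginal and
    joint occurrence counts, and an end-to-end pipeline with
    deterministic, manifest-documented outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
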