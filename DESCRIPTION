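Package: modessence
Title: Essentiality and Centrality in Modular Protein Interaction Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the relationship between protein
    essentiality and network centrality at three scales of organisation:
    individual proteins, proteins within their complexes, and whole
    functional modules. Provides readers and provenance filters for
    tab-delimited physical-interaction tables, OBO ontologies and GAF
    annotation files; module catalogues built from protein complexes and
    specific Gene Ontology biological-process terms; interaction
    classification into intramodular and intermodular edges; plain,
    normalised and semantic-similarity-weighted degree statistics; rank
    correlations, partial rank correlations and per-complex permutation
    tests; and inference of module-level cross-talk networks against a
    degree-preserving stub-rewiring null. A seeded synthetic-data
    generator produces modular interactomes with planted cross-talk
    enrichment and degree-coupled essentiality so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
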