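Package: healthqc
Title: Quality Control and Ontology-Driven Semantic Enrichment for
    Tabular Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess and improve the quality of rectangular
    patient-by-variable health datasets prior to analysis: standardisation
    of heterogeneous missing-value encodings, completeness profiling with
    clustered missingness matrices, flagging of zero-entropy variables,
    rule-based internal consistency checking, information-theoretic
    evaluation of variable merging operations, numeric encoding (ordinal,
    binary, one-hot, frequency) with a mapping reference table, and
    extraction of indicator variables from free text. Additionally performs
    semantic enrichment: dataset variables mapped to an ontology (such as
    SNOMED CT or the Gene Ontology, supplied as child-parent edge tables)
    are grouped by their most informative common ancestor and aggregated
    row-wise into meta-variables, with an information-theoretic redundancy
    audit. Includes deterministic synthetic-cohort and toy-ontology
    generators so every step can be exercised without access to restricted
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
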