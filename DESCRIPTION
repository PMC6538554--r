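Package: mdsemsim
Title: Multi-Domain Semantic Similarity for Ontology-Annotated Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes semantic similarity between resources annotated with
    concepts from several orthogonal biomedical ontologies. Single-ontology
    groupwise measures (Resnik and Lin with best-match-average, simUI,
    simGIC) are lifted into multi-domain measures either aggregatively
    (per-domain scores averaged, raw or annotation-count-weighted) or
    integratively (all ontologies merged under a common root and the
    measure applied once). Includes an OBO parser, corpus descriptive
    statistics, a multi-label k-nearest-neighbour (ML-KNN) annotation
    prediction protocol with five ranking metrics, a multi-domain
    dominance summary, and a seeded synthetic data generator for
    ontologies and annotation corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
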