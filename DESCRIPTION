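Package: circfuse
Title: Multi-Source Functional Similarity Networks for Circular RNAs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers circRNA-circRNA functional similarity by building three
    independent similarity networks -- disease semantic similarity over a
    MeSH-style disease DAG, gene similarity from skip-gram embeddings of an
    ontology axiom/annotation corpus, and sequence similarity from chaos-game
    representation (FCGR) features -- and fusing them with constrained convex
    weights tuned by grid search against circRNA-miRNA Jaccard similarity.
    Includes a synthetic-data generator with planted cluster structure,
    evaluation utilities (miRNA-similarity correlation, binned co-expression
    correlation, thresholded network export), and a pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
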