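Package: sagescape
Title: Digital Gene Expression Analysis for SuperSAGE Tag Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for SuperSAGE digital gene expression
    studies of host immune responses: simulation of tag libraries under a
    factorial exposure design, IUPAC consensus reference construction,
    26-bp tag extraction with random-barcode (UMI) PCR-duplicate removal,
    tag-to-gene assignment under uniqueness and mismatch rules,
    counts-per-million normalization, permutational MANOVA on correlation
    distances, nonmetric multidimensional scaling, negative-binomial
    exact-test differential expression with Benjamini-Hochberg correction,
    and Gene Ontology over-representation analysis with DAG propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
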