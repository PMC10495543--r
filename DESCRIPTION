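Package: readformer
Title: Transformer-Encoder Taxonomic Classification of Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for taxonomic assignment of short metagenomic sequencing
    reads (100-250 bp) with a self-attention (transformer-encoder) classifier.
    Provides canonical k-mer, character-level, locality-sensitive-hashing and
    hash-embedding tokenization schemes, sinusoidal positional encoding,
    masked multi-head self-attention with residual connections and layer
    normalization, interconnected multi-level (genus/species) classification
    heads, class-weighted cross-entropy training with early stopping, and
    paired-end inference with abundance profiling.  Includes simulators for
    taxonomy-structured genomes, coverage-balanced training read sets with a
    parametric substitution error model, and log-normal mock communities, so
    the whole pipeline can be exercised and validated at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
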