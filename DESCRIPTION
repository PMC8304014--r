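Package: scrnasim
Title: Ground-Truth-Anchored Simulation of Single-Cell RNA-Seq Raw Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates single-cell RNA sequencing raw data from a pre-defined
    ground-truth mRNA copy-number matrix. Builds a persistent sequencing
    library (cell barcode bank with Hamming-distance constraints, UMI bank,
    transcript fragment library, and a PCR amplification control ledger),
    emits error- and quality-profiled paired FASTQ at a chosen depth, and
    quantifies the reads back into a cell-by-gene count matrix via barcode
    demultiplexing and directional UMI deduplication. Includes a clustering
    benchmark harness (normalizations, PCA, several clustering algorithms)
    that scores results against the known cell labels by majority-label
    accuracy, plus dropout/low-count diagnostics and knee-curve cell calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    S4Vectors,
    class,
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
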