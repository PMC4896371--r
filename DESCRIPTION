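Package: tradisr
Title: Analysis of Transposon Directed Insertion-Site Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for transposon insertion sequencing (TIS/TraDIS) data:
    filters and trims transposon-tagged reads, maps them to a multi-replicon
    reference with a built-in seed-and-extend mapper, produces per-nucleotide
    insertion plot files viewable in the Artemis genome browser, aggregates
    read counts and unique insertion sites per gene, classifies gene
    essentiality from the bimodal insertion-index distribution with a
    two-component gamma model, and tests for condition-dependent fitness
    differences with a negative-binomial exact test under TMM normalization.
    Includes a transposon mutant library simulator that generates complete
    synthetic experiments with ground truth for validation.
License: GPL-3
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    MASS,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
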