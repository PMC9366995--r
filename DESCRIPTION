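Package: seqcomplexity
Title: Compression-Based Complexity Landscape of Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free analysis of viral genome sequences through data
    compression. Implements an adaptive finite-context-model compressor with
    inverted-repeat detection modes, normalized compression (NC), normalized
    compression capacity (NCC) and related scalar measures, minimal
    bidirectional complexity profiles with low-pass smoothing, a synthetic
    inverted-repeat mutation benchmark, taxonomy and outlier filtering,
    per-rank aggregation with annotated cladogram export, and a feature-based
    taxonomic classification harness with an analytic random-classifier
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    signal,
    MASS,
    e1071,
    class,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
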