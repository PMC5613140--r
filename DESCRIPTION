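Package: segcoex
Title: Transcription Unit Detection from Co-Expression Networks and Gene Order
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects operon-like transcription units (GTSegments) in bacterial
    genomes by combining a thresholded gene co-expression network (Spearman
    correlation with Bonferroni-adjusted p-values, optionally confirmed by the
    maximal information coefficient) with the circular order of genes on the
    chromosome. Contiguous arcs of the gene order whose extremities are
    connected inside the arc's induced subgraph are enumerated, scored by
    density (the fraction of arc members reachable from the extremities), and
    reduced to dominant segments. Includes supporting statistics for
    multi-condition expression studies: quantile normalization, detection of
    expressed elements against background probes, moderated-t differential
    expression with family-wise error control, Morisita-Horn dissimilarity,
    exclusive set intersections and enrichment tests, plus a synthetic-data
    generator with planted operons and recovery metrics for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    optparse,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    limma,
    vegan,
    jsonlite,
    withr
biocViews: Transcriptomics, GeneExpression, Network, Microarray, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
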