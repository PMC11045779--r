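Package: epmotif
Title: Expression-Predictive Motif Discovery from Gene Flanking Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact one-dimensional convolutional neural networks that
    classify genes as lowly or highly expressed from the proximal flanking DNA
    (promoter, 5' UTR, 3' UTR, terminator), interprets the fitted models with
    reference-based per-nucleotide contribution scores, aggregates
    high-importance subsequences (seqlets) into expression-predictive motifs
    (EPMs) with positional preferences, scans sequences for motif occurrences
    with exact p-values, computes class enrichment statistics, and classifies
    motif conservation across genotypes. A synthetic-genome generator with
    planted motifs provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
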