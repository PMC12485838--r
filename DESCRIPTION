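Package: clipkit
Title: PAR-CLIP Cluster Calling, k-mer Enrichment, and Motif-Conditioned
    Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a transcript-space PAR-CLIP analysis pipeline:
    T-to-C conversion cluster calling against a Poisson background estimated
    from non-T-to-C mismatches, 5-mer Z-score enrichment of cluster sequences
    against flanking background regions, scanning for a heptamer recognition
    element and its single-nucleotide variants, and motif-conditioned
    differential-expression binning (CDFs, median log2 fold changes, variant
    tolerance tiles). A synthetic-data generator produces transcriptomes,
    planted motifs, PAR-CLIP alignments with MD tags, and negative-binomial
    count matrices so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
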