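Package: equicre
Title: Integrated Regulatory-Element Annotation Pipeline for Equine Functional Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the bespoke computations of an integrated multi-omic
    annotation workflow for the horse genome: histone-anchored ROC calibration
    of ATAC-seq peak scores, iterative fixed-width peak merging into
    reproducible per-tissue and union peak sets, base-pair fold-enrichment of
    chromatin states over genic features, CTCF convergent-motif chromatin loop
    prediction, cis-regulatory-element to gene linking by within-loop Spearman
    correlation of H3K27ac signal and expression with Benjamini-Hochberg FDR
    control, long-read transcript quality-control filters (splice-match
    classification, intra-priming detection, 5'-degradation collapse), and
    accessibility-expression concordance analysis. A seeded synthetic-data
    module emulates every input with planted ground truth so each stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    edgeR,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
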