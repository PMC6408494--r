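Package: mirflux
Title: Weighted miRNA Quantification from Multimapping Small-RNA Reads,
    Ago-RIP Targetome Scoring, and qPCR Assay Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for small-RNA sequencing analysis of
    tumor-educated macrophages and related assays. Implements two-pass
    (mature, then precursor) assignment of multimapping reads to miRNA
    annotations with fractional weights summing to one per read, weighted
    count tables with depth normalization, median-of-ratios size factors
    and the fold-change/baseMean display filter, Ago-RIP-Seq double-difference
    target enrichment scoring on RPKM values, quality- and adapter-trimming of
    reads, qPCR delta-delta-Ct and standard-curve quantification, exponential
    mRNA-decay half-life regression, and simple morphometric formulas. A
    synthetic-data module generates every input (genome, annotation, reads,
    alignments, count tables, RIP experiments, decay series) with recorded
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
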