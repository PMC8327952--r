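Package: lncDiscover
Title: Discovery and Annotation of Endothelium-Enriched Long Non-Coding RNAs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a lncRNA discovery workflow for
    cell-type-resolved RNA-seq: candidate long non-coding RNAs are called
    from assembled transcript models by a filter cascade (length, six-frame
    ORF scan, coding-potential and homology hit tables, protein-coding
    overlap removal, novelty against a known-lncRNA catalog), classified by
    genomic context (promoter-associated versus long intergenic), scored
    for endothelial enrichment from FPKM fold changes between sorted
    endothelial and non-endothelial cells, and screened for translation
    with a ribosome-profiling Translation Efficiency Score. A seeded
    synthetic-data generator with a ground-truth manifest makes every stage
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    Rsamtools,
    GenomicAlignments,
    seqinr,
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
biocViews: Transcriptomics, GeneRegulation, Annotation, Sequencing,
    RiboSeq, LongNoncodingRNA
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
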