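Package: epicell
Title: Cell-Type-Specific Transcriptome and Methylome Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize differentiated cell types from matched
    RNA-seq, whole-genome bisulfite (WGBS), MeDIP-seq and histone ChIP-seq
    profiles summarized as coverage tracks. Implements exclusion-normalized
    RPKM quantification for genes, exons and introns; differential-expression
    and cassette-exon (isoform) calling between two samples with exon-junction
    support; intron-retention detection with coverage-ratio and breadth rules
    and nonsense-mediated-decay prediction; Shannon-entropy scoring of
    cell-type specificity for arbitrary expression matrices; unmethylated
    region (UMR) segmentation from per-CpG fractional methylation; calibration
    of MeDIP enrichment to absolute methylation scores by quantile mapping;
    exon-intron boundary methylation and H3K36me3 metaprofiles; and
    UMR-to-gene regulatory association with transcription-factor binding
    asymmetry statistics. A synthetic-genome simulator with planted ground
    truth (cassette exons, retained introns, UMRs, differential genes) makes
    the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
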