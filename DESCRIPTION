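Package: cocoprom
Title: Detection and Co-Regulation Analysis of Convergent Promoters from
    Strand-Specific 5'-End, 3'-End and Coverage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects convergent promoter constellations from strand-specific
    CAGE-like 5'-end tag data, annotates downstream antisense RNAs (daRNAs)
    from RNA-seq coverage and QuantSeq-like 3'-end data, and quantifies
    co-regulation of convergent transcription start site pairs across
    treatment conditions. Includes strand-specific peak calling with summit
    detection, divergent and convergent TSS pairing, quadruple assembly and
    labeling, sliding-window transcript body extension, median-of-ratios
    normalization with pseudocounted log2 fold changes, correlation and
    tissue-specificity statistics, scale-adjusted metaprofiles, and a
    synthetic-data generator that plants promoter architectures with
    correlated treatment effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    DESeq2
Config/testthat/edition: 3
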