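Package: ampliconStructure
Title: Amplicon Assembly and Structure Classification from Low-Coverage
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates copy-number segments (Control-FREEC "_CNVs" dialect)
    and structural-variant breakpoints (BreakDancer dialect) from low-coverage
    whole-genome sequencing to assemble amplified genomic segments into
    amplicons and classify each amplicon's structure as inverted duplication
    (the fold-back signature of breakage-fusion-bridge cycles), tandem repeat,
    or double minute. Includes a call-level simulator of the three amplicon
    architectures with configurable noise for end-to-end validation, cohort
    statistics for ERBB2/HER2-amplified tumours (ddPCR copy number, stage
    versus segment-count contingency with Fisher's exact test, ddPCR/lcWGS
    agreement), and writers for BED and Circos link files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    igraph,
    jsonlite,
    optparse,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
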