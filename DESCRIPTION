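Package: shortiso
Title: Discovery and Validation of 5'-Truncated Transcript Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers 5'-truncated transcript isoforms driven by internal
    alternative promoters from exon-level RNA-seq expression, and validates
    them across omics layers. Provides per-exon read counting and RPKM
    profiling, a two-block contrast caller for the truncation breakpoint,
    chromatin-signal scoring of alternative-promoter evidence (H3K27ac,
    H3K4me3, RNA Pol II, H3K27me3), stop-codon-anchored open reading frame
    prediction with protein-domain loss assessment, proteogenomic peptide
    mapping with sequence coverage and label-free XIC-area quantification,
    and negative-binomial simulators that generate ground-truth fixtures
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
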