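Package: msrrbs
Title: Simulation and Analysis of Multiplexed Single-Cell RRBS Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulator and analysis pipeline for multiplexed
    single-cell reduced representation bisulfite sequencing (msRRBS)
    libraries. Models the library architecture of early-pooled,
    barcode-adapter RRBS reads (in-silico MspI digestion, per-cell
    methylomes, bisulfite conversion, unmethylated spike-in control,
    sequencing error), and provides the inverse pipeline: exact-match
    barcode demultiplexing, structural trimming, bisulfite-aware
    alignment in MspI fragment space, per-cell CpG methylation calling
    with conversion-rate estimation, cohort analytics (pseudo-bulk
    merging, saturation curves, window matrices, correlation, metagene
    profiles, embeddings) and differentially methylated region calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rtsne,
    optparse
Config/testthat/edition: 3
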