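Package: pirnaterm
Title: Simulation and Analysis of piRNA Transcription Termination Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the genomic readouts of piRNA
    transcription termination in the C. elegans germline: classification and
    fractional counting of small-RNA reads (21U piRNAs, antisense 22G siRNAs),
    equal-occupancy density binning of the transcriptome, mismatch-tolerant
    piRNA target scanning, short-capped-RNA precursor length profiling with
    bootstrap bimodal peak estimation, 5'-end initiation-offset and
    3'-cleavage-fragment positional profiles, RNA Pol II gene-body enrichment
    classification, gene-set overlap statistics, and quantification of nuclear
    foci colocalization by Otsu segmentation. A seeded synthetic-data generator
    produces every input the pipeline consumes, so all analyses run end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    tiff,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
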