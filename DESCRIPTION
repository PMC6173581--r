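Package: readthroughr
Title: Strand-Specific Detection of Read-Through Transcripts and
    Differential Expression in Yeast RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects 3'-extended read-through transcripts from stranded
    RNA-seq alignments by calling broad coverage peaks in gene-free
    intergenic regions, filtering them by distance to the nearest
    transcription termination site (TTS) and by replicate consensus,
    quantifying transcripts with and without their 3' extensions, and
    testing counts with a negative-binomial Wald test against log2
    fold-change thresholds with Benjamini-Hochberg correction. Ships a
    stranded single-end read simulator with planted read-throughs, fold
    changes and replicate structure for end-to-end validation, plus gene
    orientation (convergent/tandem) and gene-set overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
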