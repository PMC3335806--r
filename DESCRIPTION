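Package: cistromer
Title: Cistrome-Transcriptome Integration for Hormone-Receptor ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully tested pipeline for integrating a
    transcription factor cistrome with the transcriptome it regulates,
    modelled on progesterone-receptor ChIP-seq in breast cell lines.
    Provides input-controlled peak calling with strand-shift learning,
    multiread down-weighting and swap-based false discovery estimation;
    position weight matrix scanning with exact dynamic-programming
    p-values and hormone response element strength classes; GC-matched
    hypergeometric motif enrichment and cofactor co-occurrence;
    peak-to-gene association statistics with distance-distribution
    tests; differential-expression integration with self-organizing-map
    clustering; tag-density metaprofiles; and a synthetic-data generator
    with planted ground truth against which every stage is scored.
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
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
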