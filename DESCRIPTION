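Package: tftargets
Title: Direct and Indirect Transcription Factor Target Classification
    from Knock-Down Time-Course RNA-Seq and ChIP-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates an siRNA knock-down time-course of gene expression
    with chromatin immunoprecipitation sequencing of the silenced
    transcription factor and a partner factor. Provides temporal
    differential-expression phasing (early versus late responders),
    consensus peak-summit construction with a 50-percent-of-shorter
    overlap rule, exponential distance-decay peak proximity scoring
    around transcription start sites, quadrant classification of genes
    into exclusive, dual or indirect targets, and a synthetic-data
    generator that plants the statistical structure the analysis
    assumes, so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
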