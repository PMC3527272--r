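Package: topotrans
Title: Genome-Wide Analysis of Topoisomerase-Dependent Transcription
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for genome-wide transcriptional effects of DNA
    topoisomerase deficiency in budding yeast. Provides spike-in-anchored
    normalization of expression arrays under global mRNA-level shifts, signal
    log2-ratio (SLR) statistics and deregulated-gene summaries, moving-average
    trend analysis of expression changes against per-gene covariates
    (abundance, transcriptional activity, transcript length), transcriptional
    plasticity and environmental-responsiveness statistics from profile
    compendia, hypergeometric gene-set overlap and annotation enrichment,
    TSS-aligned nucleosome occupancy meta-profiles with a nucleosome-free
    region statistic, and qPCR/ChIP fold-enrichment quantification. A
    synthetic-data generator with planted ground truth (global expression
    scaling, activity-dependent effects, class-specific plasticity and
    promoter nucleosome architecture) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
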