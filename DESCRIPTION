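Package: enhancertx
Title: Transcribed Enhancer Annotation and Enhancer-Promoter Pairing from
    Nascent Transcription Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates transcribed enhancers from strand-specific nascent
    transcription (TT-seq-like) coverage and links them to target promoters.
    Implements two-state hidden Markov model genome segmentation with a
    Poisson-log-normal emission, transcription unit classification (mRNA,
    uaRNA, conRNA, asRNA, intergenic), bidirectional and antisense enhancer
    RNA calling against chromatin-state intervals, median-of-ratios
    normalization and FPK activity matrices, transcription directionality
    and entropy/Jensen-Shannon cell-type specificity scores, correlation
    based enhancer-promoter pairing (nearest, correlated-neighboring,
    correlated-window), super-enhancer stitching, and matched-null
    resampling statistics for interaction support and SNP enrichment.
    Includes a synthetic data generator emulating the statistical structure
    of multi-cell-line nascent transcription experiments so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
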