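Package: fusegraph
Title: Fusion Transcripts and Genomic Breakpoints from Discordant RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide detection of fusion transcripts and their underlying
    genomic breakpoints from chimeric (discordant) RNA-seq alignments.
    Split reads and discordant read pairs are transformed into a breakpoint
    graph, clustered into rearrangement events, splice-variant corrected,
    filtered, and classified as exonic (splice fusion) or intronic (genomic
    breakpoint) junctions, with head-to-tail (circRNA-like) flagging.
    Includes cohort-level utilities (windowed junction matching against e.g.
    WGS breakpoints, binned junction density, locus-conditioned differential
    expression with a negative-binomial exact-style test) and a deterministic
    rearrangement/read simulator so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    withr,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
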