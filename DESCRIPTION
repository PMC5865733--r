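Package: riboTE
Title: Translational Efficiency Analysis of Ribosome Profiling Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying transcripts by translational
    efficiency (TE) from paired ribosome-footprint (FP) and fragmented
    total-RNA control (CT) sequencing libraries. Provides a seeded synthetic
    read simulator with ground truth, an exact-match short-read aligner with a
    multi-mapping cap and rRNA-model exclusion, RPKM normalization with
    replicate averaging, region-level (5'UTR/CDS/3'UTR) footprint coverage
    ratios, a negative-binomial exact test for footprint versus control counts,
    high/low-TE filtering with splice-variant collapsing, k-means clustering of
    TE trajectories under Pearson correlation distance, and organelle-homology
    flagging with chloroplast CDS profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
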