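Package: promclust
Title: Positional Clustering of Transcription-Factor Motifs in TSS-Anchored Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription-factor binding motifs with positional
    preferences relative to the transcription start site (TSS) in gapless,
    TSS-anchored blocks of promoter sequences. Sequences are scanned with
    JASPAR-style count matrices against piecewise third-order Markov
    background models with two-sided flank conditioning; per-column motif
    scores are segmented into maximal-scoring clusters with the Ruzzo-Tompa
    algorithm and assigned Karlin-Altschul and permutation p-values; cluster
    gene-groups are tested pairwise for intersection enrichment with Fisher
    exact tests against the dataset's own gene universe. Includes seeded
    synthetic-promoter generators with planted regulatory modules and
    negative-control databases so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
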