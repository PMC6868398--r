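Package: chipcooc
Title: Spike-In Normalized ChIP-Seq Quantification and Promoter Co-Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("chipcooc", "developers", email = "chipcooc@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ChIP-seq analysis with exogenous spike-in
    chromatin: partitioning and filtering of dual-genome alignments, spike-in
    ratio and per-sample scaling factors, coverage-track scaling with
    mode-subtraction background removal, consensus peak construction from
    summit-extended replicate and antibody calls, multi-factor co-occupancy
    supersets of fixed-width promoter regions, k-means classification of
    strong and weak targets, region-set signal quantification with Tukey
    notches, a spectral-count enrichment filter for AP-MS interactor lists,
    and exact hypergeometric overlap tests for differential-expression gene
    lists. Includes seeded synthetic-data generators with ground truth for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
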