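Package: pprnet
Title: Per-Sample Transcription-Factor Regulatory Networks and
    Personalized PageRank Ranking
Version: 0.1.0
Authors@R:
    person("pprnet", "developers", email = "pprnet@example.org",
           role = c("aut", "cre"))
Description: Builds one directed transcription-factor (TF) to gene
    regulatory network per sample from ATAC-seq peaks, position weight
    matrix motif scanning and enhancer-promoter link tables; ranks TFs by
    Personalized PageRank with expression-derived node and edge weights;
    stratifies samples by hierarchical clustering of per-TF z-scored
    PageRank profiles; identifies cluster-specific TFs through a
    regulatee-PCA Hotelling T-squared test with Benjamini-Hochberg
    control; and validates inferred topologies with cross-validated
    random-forest regression against a row-shuffled baseline. Includes a
    synthetic-data generator with planted two-cluster structure and
    ground truth for end-to-end benchmarking, plus a subcommand pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    yaml,
    cluster,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
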