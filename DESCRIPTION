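Package: iplscreen
Title: Integrated Pathway Scoring and RNAi Screen Analysis for Paired
    Drug-Resistant Cell Lines
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for identifying
    drug-resistance networks from paired sensitive/resistant cancer cell
    lines: per-gene differential expression (Welch t-test, Benjamini-
    Hochberg correction, fold-change gate), circular binary segmentation
    of probe-level copy-number log2 ratios with gene-level summarization,
    integrated pathway level (IPL) scoring by sum-product belief
    propagation on a signed curated pathway graph, candidate nomination
    by IPL-outlier and expression-variability filters, and RNAi viability
    screen normalization (local-regression spatial correction, negative-
    control scaling) with Wilcoxon/BH hit calling. A synthetic-data
    module generates every pipeline input with known ground truth so all
    stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
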