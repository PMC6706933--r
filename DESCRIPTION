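Package: drugzr
Title: Chemogenetic Interaction Scoring for Pooled CRISPR Drug-Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores drug-gene interactions in pooled CRISPR knockout
    drug-modifier screens. Implements the drugZ statistic (depth-normalized
    log2 fold changes, empirical-Bayes variance estimation over read-count
    neighbourhoods, guide Z-scores and gene-level normZ with two-directional
    Benjamini-Hochberg false discovery rates) together with its
    Gibbs-sampling counterpart drugGS (per-gene Normal-Gamma posterior over
    the mean guide Z-score), a negative-binomial synthetic-screen simulator
    with planted ground truth, and hypergeometric gene-set enrichment
    evaluation of hit lists. Supports paired and unpaired replicate designs
    and ships command-line entry points for each step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
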