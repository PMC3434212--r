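Package: monobead
Title: Bead-Level Microarray and qPCR Analysis of Monocyte Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for comparing monocyte transcriptomes between patient
    groups and across short-term treatment on Illumina-style bead arrays:
    bead-level outlier removal (median +/- 2 MAD), detection calls against
    negative controls, group-level transcriptional-activity filtering,
    log2-quantile normalization, Bayesian-regularized (Cyber-t) and paired
    differential expression with threshold-grid summaries, ratio-based
    hierarchical clustering with leaf-adjacency scoring, per-sample
    log2-ratio heterogeneity analysis, and a qPCR validation arm with
    replicate QC, geNorm/NormFinder reference-gene stability and
    delta-delta-Ct relative quantification. Includes a synthetic cohort
    generator with known ground truth so every stage is testable without
    microarray downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
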