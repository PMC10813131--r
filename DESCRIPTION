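Package: plvnet
Title: Phase-Locking-Value EEG Network Analysis with a Synthetic Cohort Generator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study group differences in EEG functional connectivity
    during resting state and a staged visuomotor docking task. Generates
    synthetic multichannel EEG cohorts with plantable band-specific pairwise
    phase coupling, behavioral stage times and depression-scale scores;
    preprocesses recordings (2-s segmentation, zero-phase Chebyshev band
    filtering, baseline correction, average reference, optional FastICA
    artifact removal); computes phase-locking-value (PLV) adjacency matrices
    per subject, frequency band and task stage; derives weighted small-world
    graph metrics (clustering coefficient, path length, global and local
    efficiency, node strength) and 10-region scalp averages; and contrasts
    groups edgewise and nodewise with Wilcoxon rank-sum tests under
    Benjamini-Hochberg false-discovery-rate control, including Spearman
    correlations between regional clustering and symptom scores and a
    config-driven end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
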