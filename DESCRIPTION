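Package: plaquehub
Title: Hub-Gene Discovery and Network-Proximity Drug Prioritization for
    Plaque Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for two-group plaque transcriptome
    analysis: empirical-Bayes moderated-t differential expression with
    Benjamini-Hochberg control, over-representation analysis against
    user-supplied gene-set collections, protein-protein interaction
    network construction with MCODE-style dense-module detection and
    centrality-based hub ranking, single-gene diagnostics (exact Wilcoxon
    tests, ROC/AUC, a small linear support-vector machine with
    leave-one-out scoring), single-sample gene-set enrichment (ssGSEA)
    with exact small-sample rank correlations, and a weighted
    network-proximity statistic with a permutation null for prioritizing
    drugs whose targets sit close to a disease gene set. Seeded synthetic
    generators produce inputs with known planted structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    e1071,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
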