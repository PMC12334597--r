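Package: micohost
Title: Integrative Tumor Microbiome and Host Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative analysis pipeline for paired tumor microbial
    transcript counts and host gene expression. Derives microbe-based sample
    clusters (MD-Clusters) by Spearman average-linkage hierarchical clustering
    of relative abundance, selects differentially abundant microbes between
    patient groups with t-tests and Benjamini-Hochberg FDR control, discovers
    heterologous host-gene/microbe feature clusters with high-confidence
    correlated pairs, and stratifies disease-free survival by median splits
    with Kaplan-Meier, log-rank, and Cox proportional-hazards models. Includes
    a synthetic cohort generator with a ground-truth ledger so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
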