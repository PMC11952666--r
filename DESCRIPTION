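Package: phosflow
Title: Differential Proteomics, Kinase Activity Inference and Co-Expression
    Modules for Two-Group Phosphoproteomic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-group quantitative
    proteomics and phosphoproteomics. Implements empirical-Bayes moderated
    t-statistics with fold-change thresholds expressed in multiples of a
    Gaussian standard deviation fitted to the bulk of the log2 fold-change
    distribution, permutation-based false discovery rate estimation for the
    selected feature set, protein-level normalization of phosphosite changes,
    kinase-substrate scoring from recognition motifs and phosphorylation
    dynamics with adaptive positive-unlabeled substrate prediction, kinase
    activity summaries, signed weighted co-expression network modules with
    topological-overlap clustering and eigengene/trait statistics, and
    hypergeometric / running-sum gene-set enrichment. A seeded synthetic-data
    generator with known ground truth supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    withr,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
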