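Package: metaboTask
Title: Metabolic Task Activity Scoring from Transcriptomic Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the activity of curated metabolic tasks directly from
    gene expression data using genome-scale metabolic models. Task-essential
    reaction and gene sets are derived once per model by parsimonious flux
    balance analysis; expression matrices are then converted to per-gene
    activity scores, propagated through gene-protein-reaction rules with
    min/max semantics and determinant tracking, and summarised into continuous
    and binary task activity scores per sample. Downstream statistical
    procedures include a permutation test for group similarity of task-score
    profiles, clustering of samples by binary task-activity combinations,
    one-tailed Fisher trait enrichment within clusters, and patient-level
    aggregation of cluster membership. A synthetic fixture generator produces
    toy models, tasks and expression matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    boot,
    jsonlite,
    xml2,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, Metabolomics, GeneExpression, Network,
    SystemsBiology, SingleCell
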