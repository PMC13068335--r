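Package: larconnect
Title: Late-Phase Asthma mRNA Biomarker Discovery, Multi-Cohort Evaluation
    and Cell-Specific Drug-Signature Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for blood mRNA biomarkers of the allergen-induced
    late-phase asthmatic response (LAR). Implements spirometry-based dual-responder
    classification, sparse partial least squares discriminant analysis (sPLSDA) with
    cross-validated keepX tuning and panel selection, repeated stratified
    cross-validation of PLS-DA and random-forest classifiers across multi-cohort
    bulk expression data with sex stratification and percentage-rank importance
    aggregation, empirical-Bayes batch correction and Y-chromosome sex imputation,
    pseudobulk cell-type-specific differential expression with moderated
    t-statistics, GSEA-style connectivity scoring of drug perturbation signatures,
    over-representation analysis against GMT gene-set libraries, and seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    limma,
    ranger,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    sva,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
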