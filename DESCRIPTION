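Package: toxmod
Title: Gene Network Modules and Random-LASSO Prediction of
    Chemotherapy-Induced Myelosuppression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline from germline genotypes and CTCAE toxicity grades to a
    network-derived "toxicity module" of genes and a sparse genetic prediction
    model of maximal myelosuppressive toxicity.  Implements allelic Fisher
    exact association tests, nearest-protein-coding-gene seed mapping, MCODE
    molecular-complex detection with k-core vertex weighting on a STRING-style
    protein-protein interaction network, cross-phenotype module overlap,
    expression-based enrichment diagnostics (TPM, expressed-gene permutation,
    over-representation), and a random-LASSO selection-frequency procedure
    with quantile candidate sets, ridge refit, and ROC/AUC evaluation.  A
    synthetic-data generator emulating the cohort structure the analysis
    assumes makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    VariantAnnotation,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
Config/testthat/edition: 3
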