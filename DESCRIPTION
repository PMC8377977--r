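Package: radbench
Title: Discovery and Validation of Transcriptomic Predictors of Radiosensitivity
Version: 0.1.0
Authors@R: person("radbench", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and benchmarking gene-expression predictors of
    intrinsic radiation sensitivity in cell-line screens. Fits the
    linear-quadratic survival model to clonogenic dose-response data and
    summarizes each line by SF2 (surviving fraction at 2 Gy) and normalized
    AUC; ranks genes by Spearman correlation with SF2 and runs permutation
    gene set enrichment analysis with Benjamini-Hochberg FDR control; fits
    five families of linear genomic predictors (single gene, rank-gene
    ensemble, rank-gene multivariate, minimum-redundancy maximum-relevance
    selection with exhaustive or bootstrap solution sets, and elastic net);
    and evaluates them with the concordance index under repeated 10-fold
    cross-validated pre-validation plus independent-cohort external
    validation. A synthetic radiogenomic cohort generator with planted
    signal genes and known linear-quadratic parameters makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    glmnet,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
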