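Package: depresist
Title: Drug-Response Signatures and Resistance-Target Discovery in
    Cancer Cell Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pharmacogenomic pipeline for cancer cell line
    (CCL) panels. Stratifies lines into drug-sensitive and drug-resistant
    extremes from dose-response AUC values, classifies receptor mutations
    by kinase-domain location and curated oncogenicity into an ordered
    predictive score, detects differentially expressed genes with an
    empirical-Bayes moderated t-test, scores samples with
    over-representation, permutation GSEA and single-sample GSEA,
    compares sensitivity predictors by AUROC, nominates druggable targets
    from differential CRISPR knockout dependency, clusters genes by
    perturbation-induced expression changes, and runs survival contrasts
    (log-rank, Cox). A synthetic-data generator plants known signatures,
    mutation classes, selective dependencies and cluster structure so the
    whole analysis is testable against ground truth without any external
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    mclust,
    pROC
Config/testthat/edition: 3
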