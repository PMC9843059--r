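Package: tmebenefit
Title: Tumor-Microenvironment Image Features and EGFR TKI Survival Benefit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the tumor microenvironment of lung adenocarcinoma from
    nuclei centroid maps (cell-type densities, Delaunay-graph cellular
    interaction fractions, tumor/stroma ratio), fits an elastic-net penalized
    Cox model predicting survival benefit from EGFR tyrosine kinase inhibitor
    therapy, validates it with Kaplan-Meier/log-rank and treatment-by-group
    interaction Cox models, and associates the predictive image features with
    gene expression via Spearman-ranked gene-set enrichment.  Includes
    synthetic generators for cell maps, cohorts and expression matrices so the
    full analysis is reproducible without access to clinical cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    glmnet,
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
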