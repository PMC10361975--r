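Package: dcollab
Title: Data Collaboration Analysis for Cross-Institution Diabetes Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Privacy-preserving integration of tabular health-checkup data
    from multiple institutions via data collaboration (DC) analysis: each
    institution (worker) shares only a dimension-reduced intermediate
    representation of its data together with the image of a common, artificial
    anchor matrix; a master aligns the representations into a common
    collaborative space by least squares and fits a single model on the
    stacked result. The package bundles a synthetic two-institution cohort
    generator for longitudinal checkup visits, the cleaning and diabetes
    onset labelling pipeline (per-year aggregation, observation-window and
    sparsity filters, mean/mode imputation, ordinal encoding), the DC core
    (PCA/SVD intermediate maps, anchor generation, collaboration maps), and a
    bootstrap evaluation harness comparing individual, middle-representation,
    and DC analyses with L1-penalised logistic regression and gradient-boosted
    trees under shrinking local sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    xgboost,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
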