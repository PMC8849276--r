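Package: csmomics
Title: Matched Case-Control Multi-Omics Discovery of Mortality Signatures
    in Complicated Severe Malnutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for matched case-control multi-omics
    discovery studies of inpatient mortality in complicated severe
    malnutrition: propensity-score matching with balance diagnostics,
    targeted-metabolomics quality control (QC-sample CV filter, detection
    filter, LOD/2 imputation), proteomics missingness filtering, kNN
    imputation and empirical-Bayes batch correction, per-analyte
    conditional logistic screening with Benjamini-Hochberg FDR and
    metabolite-ratio analysis, bootstrap elastic-net stability selection,
    multilevel PLS-DA with cross-validated AUC, misclassification and DQ2,
    Fisher-z differential correlation networks, and similarity network
    fusion with spectral clustering. Includes a synthetic cohort generator
    with planted ground truth so every stage is testable without access to
    patient-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    cluster,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    sva,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
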