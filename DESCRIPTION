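Package: CoxenPredict
Title: Single-Drug Chemosensitivity Biomarkers by Coexpression Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discovers drug-sensitivity-associated genes on cancer cell-line
    panels, triages them by COXEN (COexpression ExtrapolatioN) second-order
    correlation against patient tumor cohorts, trains per-drug
    principal-component regression chemosensitivity models strictly in vitro,
    converts patient prediction scores to rank percentiles, and flexibly
    combines per-drug scores into combination-chemotherapy predictors of
    pathological response and censored survival. Ships a latent-factor
    synthetic-data generator with full ground-truth manifests so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'simulate.R'
    'association.R'
    'coxen.R'
    'modeling.R'
    'evaluation.R'
    'io.R'
    'pipeline.R'
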