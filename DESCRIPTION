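Package: rascl
Title: Random Slice Contrastive Learning for Retinal OCT B-Scan
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Self-supervised contrastive pre-training for multi-slice
    retinal optical coherence tomography (OCT) volumes, using neighboring
    B-scans within an eye as positive pairs (random slice contrastive
    learning), followed by frozen-encoder fine-tuning and cross-validated
    ensemble averaging for full-thickness macular hole versus epiretinal
    membrane classification. Includes a synthetic layered-retina phantom
    generator, covariate-balanced stratified splitting, confusion and ROC
    metrics, gradient saliency maps, and a one-command experiment pipeline,
    all runnable at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
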