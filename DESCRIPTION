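Package: fluordx
Title: Dense Neural Network Classification of Multispectral Skin Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorescence-spectroscopy-based skin cancer diagnostics:
    a synthetic generator for labelled multispectral skin autofluorescence
    cohorts (collagen, NADH, FAD and porphyrin emission bands with reduced
    band intensities in basal cell carcinoma), a from-scratch dense neural
    network binary classifier trained by stochastic gradient descent with
    momentum, Nesterov acceleration, inverse-time learning-rate decay,
    dropout and early stopping with best-model checkpointing, a repeated
    random-split case-level cross-validation protocol, and diagnostic
    metrics (inclusive-threshold spectrum classification, strict-majority
    patient aggregation, sensitivity, specificity, ROC and AUC) summarised
    as order statistics over cross-validation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
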