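Package: lai
Title: Liver Aging Index from Noninvasive Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and validation of a liver-specific biological age,
    the Liver Aging Index (LAI), from routine clinical, blood and
    transient-elastography biomarkers. Implements the two-step procedure:
    per-category elastic-net Cox risk scores for liver-related events, and a
    left-truncated Cox-Gompertz mortality model on the age timescale whose
    sex-specific mortality-rate doubling time converts the hazard ratio
    between the biomarker-informed and age-only models into equivalent years
    of liver aging acceleration (LAA). Includes a synthetic cohort generator
    with a latent liver-aging factor, an evaluation battery (Pearson/RMSE/MAE
    agreement, AUROC with DeLong comparison, Cox hazard ratios per SD,
    Kaplan-Meier and log-rank), JSON model bundles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    flexsurv,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
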