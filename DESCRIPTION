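Package: flairsir
Title: FLAIR Signal-Intensity Ratio Analysis of the Stroke Onset Window
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative estimation of ischemic stroke lesion age from
    multimodal MRI. Computes apparent diffusion coefficient (ADC) maps
    from two-b-value diffusion-weighted imaging, segments the acute
    lesion by ADC thresholding, mirrors the region of interest into the
    contralateral hemisphere, and derives the FLAIR signal-intensity
    ratio (SIR) used to classify symptom onset within versus beyond the
    4.5 hour thrombolysis window. Includes a seeded synthetic cohort and
    MRI phantom generator, contingency-table diagnostics, empirical ROC
    curves with DeLong variance and paired AUC comparison, logistic
    regression with backward stepwise selection, hierarchical block
    regression with R-squared-change F tests, and counterfactual
    mediation analysis of the SIR to onset-window pathway through large
    vessel occlusion.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
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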