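Package: st1t2ratio
Title: Standardized T1w/T2w Ratio Mapping and Cohort Statistics for
    Normal-Appearing White Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for standardized T1w/T2w
    (sT1w/T2w) ratio mapping of normal-appearing white matter. Generates a
    fully synthetic two-group structural MRI cohort (tissue label phantoms,
    T1w/T2w intensity volumes with scanner gains, smooth bias fields and
    focal lesions, plus a demographic/clinical subject table), performs
    bias-field correction and lesion-aware mask arithmetic, computes classic
    T1w/T2w and standardized (T1w - sT2)/(T1w + sT2) ratio maps with
    per-tissue median extraction, and runs the cohort statistics battery:
    coefficient-of-variation equality testing (asymptotic chi-square),
    Welch t-tests, chi-square tests, Pearson correlation, and backward
    stepwise ordinary-least-squares covariate models with AIC selection and
    Cook's distance diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
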