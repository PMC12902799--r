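Package: hemodyn
Title: Model-Based Cerebral Hemodynamic Indices from Spontaneous Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates dynamic cerebral autoregulation and cerebrovascular CO2
    reactivity from short resting recordings of beat-to-beat arterial blood
    pressure, breath-to-breath end-tidal CO2, transcranial Doppler blood
    velocity and near-infrared-spectroscopy tissue oxygenation. A two-input
    linear dynamic model is fitted per subject with the Laguerre expansion
    technique; cohort principal dynamic modes are derived by singular value
    decomposition of the kernel ensemble; per-subject mode gains are converted
    into APOE-stratified log-likelihood-ratio indices (DVR, DCA, COCR, COPR
    and composite-COR) and physiological step-response indices; and the
    indices are related to tabular neuroimaging outcomes through a
    covariate-adjusted standardized regression battery with Tukey and
    Bonferroni multiplicity control. Includes a synthetic-cohort generator
    with known ground-truth kernels and effect sizes so every stage is
    testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
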