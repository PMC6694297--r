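Package: rsnlong
Title: Longitudinal Resting-State Network Analysis by Group ICA and Dual Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal resting-state fMRI network
    analysis in small-animal cohorts: temporal preprocessing (volume discard,
    spatial smoothing, polynomial detrending and motion-parameter regression,
    voxelwise z-scoring, Hamming-window FIR band-pass), temporal-concatenation
    group spatial ICA with template-based component labeling, two-stage dual
    regression yielding subject network time-series and spatial maps,
    per-network amplitude and shape metrics, default-mode-network subnetwork
    decomposition by spatio-temporal matching against a high-order ICA, and a
    longitudinal statistics layer (linear mixed-effects models with subject
    random intercepts, per-timepoint Kruskal-Wallis tests with
    Benjamini-Hochberg correction, and Spearman brain-behavior correlations).
    Includes a synthetic 4D cohort generator with known ground truth so every
    stage has a recoverable answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
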