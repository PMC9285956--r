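Package: tepnet
Title: Directed Network Analysis of TMS-Evoked EEG Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying cortical network responses to
    transcranial magnetic stimulation (TMS) with multichannel EEG. Provides a
    synthetic cohort generator with planted lagged coupling networks and
    paired-pulse suppression, TMS-EEG preprocessing (zero-phase FIR bandpass
    and notch filtering, epoching, de-meaning, amplitude-based artifact
    rejection), a long-interval cortical inhibition (LICI) statistic from
    rectified areas under averaged evoked potentials, directed functional
    connectivity graphs built from lag-maximised Pearson cross-correlations
    with an absolute edge threshold, global graph metrics (mean degree,
    clustering coefficient, local and global efficiency on directed
    distances), and the group-level statistical layer (three-way mixed ANOVA
    with partial eta squared and Sidak-adjusted simple effects, z-scored
    binomial logistic regression with inverted odds ratios and Nagelkerke R
    squared, ROC AUC discrimination, and clinical correlations).
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
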