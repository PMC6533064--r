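Package: conflictr
Title: Multimodal Analysis of Motor Inhibition During Response Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying non-selective motor
    inhibition during response conflict. Provides synthetic generators for
    Simon-task and stop-signal behavior (independent-race model with a
    staircased stop-signal delay), scalp EEG mixtures with a fronto-central
    low-frequency inhibition source, STN-M1 local field potential pairs with
    transient beta-band coupling, and TMS-evoked EMG sweeps; and the matching
    analysis stack: integration-method SSRT estimation, filter-Hilbert
    time-frequency decomposition with dB-baselined event-related spectral
    perturbations, independent-component selection and backwards-from-peak
    P3 onset detection, single-trial time-frequency regression with
    Benjamini-Hochberg FDR control, phase-locking value and spectral Granger
    prediction from bivariate autoregressive models, and motor-evoked-potential
    quantification.
License: MIT + file LICENSE
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
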