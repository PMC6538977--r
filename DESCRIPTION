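Package: anesdepth
Title: Anesthetic Depth Analysis for Neonatal LFP and Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discontinuous neonatal brain activity under
    general anesthesia: detection of active periods (bursts) and multi-unit
    activity in local field potential recordings, spectral and complexity
    metrics (Welch power spectra, modulation index, imaginary coherence,
    pairwise phase consistency, aperiodic 1/f slope, sample entropy),
    artifact scoring and envelope features for infant scalp EEG, per-minute
    feature engineering, and a resampled support-vector model that predicts
    anesthetic concentration from electrophysiological features. Includes a
    synthetic-data generator that emulates neonatal mouse LFP, juvenile mouse
    LFP and infant EEG sessions with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
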