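Package: fulcrum
Title: Closed-Loop Vagus Nerve Stimulation Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for closed-loop vagus nerve stimulation
    (VNS) titrated to the neural fulcrum, the operating point at which
    stimulation leaves heart rate near baseline. Provides a synthetic
    Lead-I-style ECG and left-ventricular-pressure generator with a
    prescribed instantaneous heart-rate profile; the real-time heart-rate
    extraction chain (linear-phase FIR bandpass, adaptive R-peak detection,
    5-second windowed medians); a calibrated dose-response plant standing in
    for the anesthetized subject; the state-based controller that steps one
    stimulation parameter (duty cycle or frequency) per rest phase; a
    closed-loop orchestrator with reproducible run records; Mann-Kendall
    trend statistics on per-epoch bradycardia magnitudes; and equivalent-
    circuit modelling of the nerve-cuff electrode impedance with
    Levenberg-Marquardt spectrum fitting, stimulation pulse patterns, and
    charge-per-pulse estimates.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
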