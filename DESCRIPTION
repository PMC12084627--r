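Package: pupilarousal
Title: Multimodal Analysis of Pupil-Biofeedback Arousal Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pupil-based biofeedback studies of
    central arousal. Implements online pupil-feedback scoring, offline
    pupillometry preprocessing and modulation indices, EEG Welch spectra
    with aperiodic (1/f spectral slope) parameterization, ERP epoching
    with spatiotemporal cluster-based permutation statistics, cardiac
    heart-rate and RMSSD indices, TMS motor-evoked-potential extraction
    with background-EMG exclusion rules, and the accompanying
    repeated-measures statistical layer. A seeded synthetic cohort
    generator reproduces the trial structure of three biofeedback
    experiments (TMS, EEG, auditory oddball) with configurable condition
    effects and a shared latent arousal factor, so every stage is testable
    end to end without access to human raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
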