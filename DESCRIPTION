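Package: perafr
Title: Percent Amplitude of Fluctuation Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise percent amplitude of fluctuation (PerAF) analysis of
    resting-state BOLD fMRI, with the surrounding group-analysis pipeline:
    initial-volume discard, motion-based subject exclusion, mean-preserving
    linear detrending, Gaussian spatial smoothing, subject-level PerAF and
    mean-standardized PerAF maps, voxel-wise two-sample t contrasts with
    Monte-Carlo cluster-extent correction, ROI mean extraction, ROC/AUC group
    discrimination with bootstrap or DeLong confidence intervals, and
    brain-behavior Pearson correlation. Includes a seeded synthetic-cohort
    generator (band-limited oscillatory signal, AR(1) noise, planted regional
    amplitude effects, phenotypes with specified correlation to regional
    amplitude) so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
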