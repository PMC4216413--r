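Package: somatomap
Title: Somatotopic Mapping of Fingertip Representations from Event-Related and
    Phase-Encoding fMRI
Version: 0.1.0
Authors@R:
    person("Somatomap", "Developers", email = "somatomap@example.org",
           role = c("aut", "cre"))
Description: Single-subject analysis of fingertip somatotopy in primary
    somatosensory cortex from 7T BOLD time series. Implements traveling-wave
    (phase-encoding) coherence and phase mapping with fingertip ROI definition,
    a two-step canonical-HRF general linear model (ordinary least squares,
    per-subject hemodynamic timing estimation, generalized least squares with
    Tukey-tapered tile-wise noise autocorrelation), finite-impulse-response HRF
    deconvolution, adaptive family-wise-error and false-discovery-rate multiple
    testing with least-squares estimation of the number of true nulls,
    activation-overlap statistics, vein masking from susceptibility phase
    images, cortical-surface utilities, and a synthetic-data generator that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
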