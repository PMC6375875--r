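Package: musupp
Title: Mu/Alpha Rhythm Suppression Analysis for EEG Action-Observation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of event-related desynchronization of the
    8-13 Hz mu/alpha rhythm in multichannel EEG: preprocessing (resampling,
    high-pass and line-noise filtering, kurtosis-based bad-channel detection
    and interpolation, common-average referencing), within-trial late/early
    band-power log-ratio suppression scores over central and occipital
    electrode clusters with scaled-MAD trial rejection, repeated-measures
    ANOVA with sphericity checking and FDR-corrected pairwise contrasts, and
    a spherical-head standardized minimum-norm (sLORETA-style) distributed
    source contrast with max-statistic permutation correction. Includes a
    synthetic-EEG generator with known injected suppression effects so every
    stage of the pipeline can be verified against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
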