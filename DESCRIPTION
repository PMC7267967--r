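Package: lamcal
Title: Laminar Calibrated BOLD fMRI with Resting-State Fluctuation
    Amplitude Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for depth-resolved (laminar) calibrated
    BOLD fMRI at high field. Implements equivolume cortical layering on a
    2D ribbon, resting-state fluctuation amplitude (RSFA) in standard
    frequency bands, hypercapnia signal-change amplitude, the modified
    Davis model and its inversion for the calibration factor M,
    BOLD-correction of interleaved VASO acquisitions, and RSFA-based
    normalization of laminar BOLD profiles against CBV-weighted VASO
    profiles. Ships a synthetic laminar VASO/BOLD session generator with
    per-lamina ground truth (baseline venous CBV, cerebrovascular
    reactivity, true M) so every stage of the pipeline can be validated
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
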