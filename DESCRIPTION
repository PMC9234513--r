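Package: synatp
Title: Semiautomated Quantification of Presynaptic ATP from Dual
    Luminescence-Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel (bioluminescence and
    mCherry fluorescence) time-lapse imaging of the Syn-ATP presynaptic
    ATP reporter in cultured neurons. Detects image background by
    two-cluster k-means on block-median-downsampled luminescence frames,
    locates and excludes the neuronal cell body with a sliding-window
    search, and computes per-timepoint background-corrected
    luminescence-over-fluorescence (L/F) traces with EMCCD dark-current
    quality control, EM-gain adjustment, and pH correction. Includes
    cohort statistics (baseline variability, combined-population
    z-scores, average traces) and a synthetic dual-channel scene
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
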