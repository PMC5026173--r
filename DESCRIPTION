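Package: xeventmap
Title: Hyperpolarized Xenon-129 Ventilation Challenge MRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of hyperpolarized xenon-129 ventilation
    MRI under bronchoconstrictive (methacholine) challenge. Provides a
    digital lung phantom and variable-flip-angle FLASH acquisition
    simulator with Rician-consistent k-space noise, sine-bell-squared
    apodized Fourier reconstruction, background-ROI based lung
    segmentation and signal-to-noise estimation, normalized global signal
    intensity curves, absolute and relative intensity difference maps with
    heterogeneity summaries, noise-consistency monitoring, Bland-Altman
    method agreement, and dose-response group comparison by two-way ANOVA
    with Bonferroni-corrected per-dose contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    RNifti,
    yaml,
    png,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
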