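Package: especkle
Title: Endoscopic Laser Speckle Contrast Analysis of Tissue Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for endoscopic laser speckle contrast
    imaging (eLASCA) of tissue perfusion through a fiber-bundle probe.
    Computes spatial speckle-contrast maps and region-averaged contrast time
    series from raw dual-wavelength (660/830 nm) image stacks, removes the
    static fiber-bundle honeycomb artifact with a radially symmetric 2-D
    Butterworth low-pass filter, extracts cardiac and respiratory rates from
    the detrended, uniformly resampled contrast signal by FFT peak
    attribution, maps relative tissue oxygenation ratiometrically and as
    modified Beer-Lambert chromophore concentration changes, and detects
    vascular occlusion onset and release as level shifts in the contrast
    series. Ships a seeded synthetic dual-wavelength speckle acquisition
    simulator with known physiological ground truth (correlation-time
    modulation, Beer-Lambert intensity forward model, honeycomb overlay,
    12-bit detector noise) so the whole chain is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
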