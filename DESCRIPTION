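Package: ppgbias
Title: Skin-Pigmentation Bias in Pulse Oximetry from Layered Tissue Optics and PPG Signal Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing how skin pigmentation biases pulse
    oximetry. Implements a spectral forward model of LED light transmitted
    through pigmented layered tissue (melanin in the epidermis, oxy- and
    deoxyhemoglobin in the dermis), a synthetic generator of paired
    pigmented/nonpigmented photoplethysmography (PPG) recordings during a
    controlled deoxygenation ramp, a digital signal-processing pipeline with
    windowed Fourier AC/DC/high-frequency decomposition, five signal-quality
    indices with exclusion thresholds, and the modulation-ratio and
    pigmentation-stratified regression statistics (paired slope tests and
    pooled difference regressions against arterial-blood-gas oxygen
    saturation).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
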