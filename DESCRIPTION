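Package: ramanmap
Title: High-Wavenumber Raman Tissue-Map Analysis for Tumor Margin Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for high-wavenumber (2500-4000 1/cm) Raman
    hyperspectral maps of resected tissue sections, aimed at discriminating
    squamous cell carcinoma from surrounding non-cancerous tissue. Provides
    spectral preprocessing (cosmic-ray removal, iterative polynomial
    autofluorescence subtraction, intensity-based quality gating), per-pixel
    water-concentration mapping from the OH/CH band ratio, extended
    multiplicative scatter correction (EMSC) with a water interferent,
    PCA-LDA classification of the CH-stretching region with
    leave-one-map-out model selection, ROC/Youden evaluation with a
    per-tissue false-positive breakdown, and a synthetic hyperspectral map
    generator that emulates the statistical structure of annotated ex-vivo
    tissue maps for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
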