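Package: firspec
Title: Hyperspectral Chemometrics for Conifer Needle Chlorophyll and Water Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A calibration pipeline for estimating needle leaf chlorophyll
    content (LCC, mg/g) and needle leaf water content (LWC, fraction) of
    conifer seedlings from near-infrared hyperspectral reflectance images
    (870-1720 nm, 512 bands). Covers ENVI cube input/output, white/dark
    reflectance calibration, canopy masking and region-of-interest mean
    spectra, wet-lab trait formulas, spectral preprocessing
    (Savitzky-Golay smoothing, standard normal variate, multiplicative
    scatter correction), characteristic-wavelength selection by the
    successive projections algorithm (SPA) and competitive adaptive
    reweighted sampling (CARS), calibration models (PLSR by NIPALS,
    epsilon-SVR, single-hidden-layer neural networks), and a
    calibration/prediction evaluation report. Includes a synthetic
    drought-gradient spectra generator so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
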