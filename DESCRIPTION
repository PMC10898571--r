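Package: DiffuseRaman
Title: Model-Based Optimization of Diffuse Raman Spectroscopy for
    Subsurface Collagen Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and evaluating diffuse Raman spectroscopy
    (DRS) measurements of thin collagen layers around subcutaneous implants,
    such as the fibrotic capsule formed during the foreign body response.
    Provides a layered digital phantom with an implant disk and collagen
    slab, a diffusion-approximation photon transport solver with adjoint
    detector sensitivities, a shot-noise signal-to-noise (SNR) model for the
    910-950 cm-1 collagen band, constrained source/detector geometry search
    under the skin maximum permissible exposure limit, limit-of-detection
    estimation, a spectral calibration pipeline (polystyrene-band
    normalization, difference spectra, partial least squares with
    leave-one-out validation, band-area regression), and a synthetic Raman
    spectrum generator with Poisson shot noise for end-to-end studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    mixOmics,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
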