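Package: flimkit
Title: Simulation and Analysis of Spectrally Resolved Fluorescence
    Lifetime (FLIM/TCSPC) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for time-correlated single photon counting (TCSPC) and
    fluorescence lifetime imaging microscopy (FLIM): simulation of
    multi-exponential decays with instrument-response convolution,
    repetition-rate wraparound, detector pile-up and solvent-relaxation
    wavelength dependence; periodic n-exponential reconvolution fitting
    with intensity-weighted mean lifetimes and photon-count quality
    control; spectrally resolved lifetime profiles and generalized
    polarization; fit-free phasor analysis with instrument-response
    calibration; and whole-image or ROI pooling of FLIM images, with
    plain-text and TIFF interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'probes.R'
    'simulate.R'
    'reconvolve.R'
    'fit.R'
    'spectral.R'
    'phasor.R'
    'image.R'
    'io.R'
    'pipeline.R'
    'flimkit-package.R'
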