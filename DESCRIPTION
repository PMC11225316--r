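Package: duospec
Title: Resolution and Quantification of Two-Component Overlapped UV Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous quantification of two spectrally overlapped
    analytes (a ciprofloxacin-like and an ornidazole-like component) from
    UV absorption spectra. Provides wavelength-grid spectrum containers
    with CSV and JCAMP-DX input/output, a Beer-Lambert synthetic mixture
    generator with controlled noise, Fourier self-deconvolution with
    zero-crossing calibration, ratio-spectra mean-centering calibration,
    feed-forward neural calibration trained by Levenberg-Marquardt and
    Bayesian-regularization backpropagation, prediction-quality and
    ICH-style validation statistics, method-comparison tests, and
    green-chemistry (modified eco-scale penalty points and RGB-12
    whiteness) scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra-core.R'
    'io.R'
    'synthetic-data.R'
    'fsd.R'
    'ratio-mc.R'
    'ann.R'
    'validation-stats.R'
    'greenness.R'
    'pipeline.R'
    'duospec-package.R'
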