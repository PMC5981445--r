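Package: ftshg
Title: Fourier-Transform Quantification of Second-Harmonic Generation
    Images of Fibrillar Collagen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of second-harmonic generation (SHG)
    micrographs of fibrillar collagen and of other oriented-texture
    grayscale images. Implements grid-based area-fraction density,
    two-dimensional Fourier angular profiling with its peak spectral
    intensity, spectral anisotropy via the axis ratio of the equivalent
    ellipse of the binarized magnitude spectrum, structure-tensor
    classification of grid cells into anisotropic, isotropic and dark
    regions with preferred fiber orientation, and before/after
    percent-change statistics with pooled-variance two-sample t tests.
    A synthetic fiber-phantom generator with ground truth supports
    validation of every stage, including emulation of cross-linking-like
    and wet-mode-damage-like structural change.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'density.R'
    'spectral.R'
    'orientation.R'
    'comparison.R'
    'phantom.R'
    'pipeline.R'
    'plots.R'
    'utils.R'
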