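Package: LaminaShape
Title: Quantification and Classification of 3D Nuclear Lamina Shape
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the three-dimensional shape of the nuclear
    lamina from confocal Z-stacks and to classify cell populations from the
    resulting descriptors. The package segments the lamina as a closed
    triangulated surface, computes three per-cell shape descriptors (mean
    normalized intensity, intensity skewness, and normalized average absolute
    Gaussian curvature), and separates labeled populations with a Fisher
    linear discriminant evaluated by leave-one-out cross-validation with
    permutation-based significance. A synthetic nucleus simulator with
    analytic ground truth (spherical-harmonic wrinkling, blebs, intensity
    hotspots, confocal-style anisotropic blur and shot noise) supports
    validation end to end, and a FRAP module estimates recovery half-times
    and immobile fractions from bleach-region time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    Matrix,
    tiff,
    xml2,
    jsonlite,
    yaml,
    withr,
    e1071,
    pracma,
    ggplot2,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    minpack.lm
biocViews: CellBiology, Classification, Software, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LaminaShape-package.R'
    'RcppExports.R'
    'classification.R'
    'features.R'
    'frap.R'
    'mesh.R'
    'pipeline.R'
    'segmentation.R'
    'sph-harm.R'
    'stack-io.R'
    'synthetic.R'
    'utils.R'
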