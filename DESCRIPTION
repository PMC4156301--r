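Package: tomodart
Title: Multiresolution Discrete Algebraic Reconstruction for Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete tomography reconstruction from few-view and
    limited-angle (missing wedge) projection data. Implements a
    ray-driven Joseph forward/back projector for parallel- and fan-beam
    geometries, SIRT with masked (fixed-pixel) updates, the Discrete
    Algebraic Reconstruction Technique (DART), and its coarse-to-fine
    multiresolution variant (MDART) that runs DART on successively
    halved pixel sizes, carrying each reconstruction to the next finer
    grid by bilinear interpolation. Ships parametric phantom generators
    (disk with holes, Siemens star, multi-grey ellipse composites,
    structured binary objects), a Poisson photon-noise model for
    sinograms, segmentation-error metrics (relative number of
    misclassified pixels), and a benchmark runner for projection-count,
    missing-wedge and photon-count sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
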