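Package: kamcorr
Title: Correlation-Based Ab Initio 3D Reconstruction for Single-Particle X-Ray Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the 3D diffraction intensity volume and real-space
    density of a single particle from many randomly oriented X-ray
    free-electron-laser diffraction snapshots, without orientation
    determination. Double, triple and quadruple angular correlations are
    accumulated over the pattern stack, corrected for photon shot noise,
    detector (Fano and electronic) noise and isotropic scattering
    backgrounds, expanded into Fourier-Legendre series per radial shell
    pair, and eigen-decomposed into per-degree basis vectors. The basis
    vectors are aligned by minimizing a triple-correlation constraint error
    over restricted unitary matrices parameterized by hyperspherical
    angles, using progressive Levenberg-Marquardt least squares with
    multi-trial averaging, followed by iterative phase retrieval. Includes
    a full synthetic-data simulator (flat-Ewald slicing, Poisson and
    detector noise, Compton and instrument backgrounds, partial-pattern
    masks) and validation tools (Fourier shell correlation, correlation
    NRMSE maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
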