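Package: nirsarray
Title: Simulation and Statistical Comparison of Sparse and High-Density
    fNIRS Optode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing sparse grid and high-density hexagonal
    functional near-infrared spectroscopy (fNIRS) optode arrays on synthetic
    data with known ground truth. Builds planar probe geometries, computes
    channel-vertex sensitivity matrices from a semi-infinite diffusion
    Green's function, simulates two-wavelength block-design recordings with
    superficial physiology and motion artifacts, and implements a standard
    channel-space processing chain (pruning, optical density, spline plus
    Savitzky-Golay motion correction, low-pass filtering, the modified
    Beer-Lambert law, and a GLM with a Gaussian temporal basis and
    short-separation regression). Images are reconstructed on brain and
    scalp surfaces with spatially variant Tikhonov regularization, and
    arrays are compared with block-delta t-statistics, paired tests, and a
    cluster-based sign-flip permutation test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
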