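Package: holotomo
Title: Phase Retrieval and Tomographic Reconstruction for X-Ray Holo-Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for propagation-based X-ray phase-contrast imaging and
    holo-tomography. Implements Fresnel free-space propagation with astigmatic
    (per-axis) Fresnel numbers, quantitative phase retrieval in the
    direct-contrast regime (Paganin, generalized Paganin, modified Bronnikov,
    Bronnikov-aided correction) and the holographic regime (CTF with two-level
    frequency regularization, constrained CTF via ADMM, nonlinear Tikhonov and
    smoothed-TV Tikhonov via proximal gradient methods, alternating
    projections), raw-frame preprocessing (interpolated and PCA flat-fielding,
    faulty-pixel repair, least-curvature background removal), parallel-beam
    tomography (FBP, SIRT) with per-projection geometry, center-of-rotation
    estimation, iterative reprojection alignment, sinogram ring removal
    (additive and wavelet-FFT), and a phantom-based simulator for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
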