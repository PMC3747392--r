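Package: voxreg
Title: Multi-Resolution Affine Registration and Interpolation Assessment for 3D Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the choice of interpolation kernel and
    intensity cost function affects upsampling quality and intensity-based
    affine registration of 3D medical-image volumes. Implements eight
    separable interpolation kernels (nearest neighbour, trilinear, cubic,
    quintic and heptic Lagrange, 3rd- and 4th-order B-spline, windowed
    sinc), four similarity costs (least squares, correlation ratio,
    normalized cross-correlation, normalized mutual information), a
    coarse-to-fine 12-degree-of-freedom affine optimizer with centre-of-mass
    initialization and candidate retention across pyramid levels, a
    multi-tissue synthetic head phantom with a configurable degradation
    chain (decimation, rigid motion, blur, noise), and registration quality
    metrics (MSE, PSNR, Shannon and joint entropy, joint histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
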