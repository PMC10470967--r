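Package: mesr
Title: Sparse-Domain Super-Resolution for Tomographic Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for super-resolving noisy tomographic reconstructions with a
    coupled low-/high-resolution dictionary pair learned in the sparse domain.
    Includes a synthetic tomography stack (parametric ellipse and breast-tissue
    phantoms, parallel-beam Radon projection, filtered back projection, SART
    iterative reconstruction, and ring-array ultrasound data rearrangement),
    the image enhancement operators used to build denoised high-resolution
    detail images (bilateral filtering, brightness-preserving dynamic histogram
    equalization, singular value equalization, guided filtering), K-SVD
    dictionary learning with orthogonal matching pursuit coding, and the
    image-quality metrics (PSNR, entropy, average gradient) used to evaluate
    reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    tibble,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
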