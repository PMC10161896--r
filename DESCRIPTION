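Package: destriper
Title: Ring Artifact Correction for Tomographic Sinograms with a
    Wavelet-Domain Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Removes stripe artifacts from tomographic sinograms - the
    sinogram-domain counterpart of ring artifacts in reconstructed CT
    slices. A sinogram is decomposed into its four single-level Haar
    wavelet sub-bands, a 14-layer residual convolutional network predicts
    the stripe component of each sub-band, and the cleaned sinogram is
    recovered by the inverse transform. Includes the synthetic training
    protocol (seeded phantoms, parallel-beam Radon transform, random
    stripe injection), a composite wavelet-MSE plus along-stripe
    smoothness training objective, transfer-learning fine-tuning, the
    combined wavelet-Fourier filtering baseline, filtered back projection,
    and a PSNR/SSIM evaluation harness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
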