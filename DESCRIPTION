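Package: dictmri
Title: Dictionary-Learning Reconstruction and Staging Concordance for Accelerated MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compressed-sensing reconstruction of undersampled
    magnetic-resonance images by three dictionary-learning routes: an analytic
    (total-variation) route, a synthetic patch dictionary learned by K-SVD-style
    alternating minimization with orthogonal-matching-pursuit sparse coding, and
    a small convolutional network ("deep dictionary") trained by stochastic
    gradient descent with weight decay. Includes image preprocessing operators
    (dual-tree complex wavelet denoising, morphological top-hat transforms,
    spatial and frequency-domain enhancement), synthetic phantom / k-space /
    staging-cohort generators, PSNR and SSIM image-quality metrics, and
    diagnostic concordance statistics (per-stage sensitivity and specificity,
    coincidence rate, Pearson chi-square, Cohen's kappa) for imaging-versus-
    pathology tumor staging tables. A command-line front end and an experiment
    runner reproduce method-by-sampling-rate benchmark tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    tiff,
    RNifti
Config/testthat/edition: 3
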