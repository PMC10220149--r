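Package: sr4dflow
Title: Super-Resolution of 4D Flow MRI Velocity Fields from Synthetic
    Regurgitant Jets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to train and evaluate x4 super-resolution networks for
    phase-contrast (4D flow) MRI of aortic regurgitation. Synthesises
    high-resolution jet flow fields through a catalogue of Venturi-style
    constriction geometries, forward-models low-resolution MR acquisitions
    with velocity encoding (VENC) phase wrapping, k-space truncation and
    SNR-controlled complex noise, generates paired training patches with
    rotation augmentation, and provides three 3D convolutional
    super-resolution architectures (residual, dense and cross-stage-partial
    blocks) with a fluid/non-fluid split loss, Adam training, patch-stitched
    whole-volume prediction and velocity-field error metrics (relative speed
    error, per-component RMSE and SSIM, regression and Bland-Altman
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
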