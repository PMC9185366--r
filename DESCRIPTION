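Package: synthmr
Title: Paired CT-to-MR Image Synthesis with a Cycle-Constrained Conditional GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-modality medical image translation: synthesis of
    magnetic resonance (MR) slices from aligned computed tomography (CT)
    slices with a conditional generative adversarial network. Provides the
    residual encoder-decoder generator and its inverse, conditional patch
    discriminators, a four-term training objective (adversarial, voxel-wise
    L1, perceptual feature matching, and a von Mises-Fisher cosine
    re-identification loss), an alternating training loop with a linear
    learning-rate decay schedule, a five-metric paired-image evaluation suite
    (MAE, RMSE, PSNR, SSIM, PCC) with box-plot summaries, and a synthetic
    phantom generator producing co-registered CT/MR pairs with a known
    ground-truth mapping so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    withr,
    png,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
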