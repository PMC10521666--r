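Package: tvae
Title: Temporal Variational Autoencoders for Longitudinal Bone Image
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a temporal variational autoencoder to ordered sequences
    of grayscale image slices and generates plausible future frames.
    The model couples a recurrent learned-prior estimator, a recurrent
    future predictor and a training-only latent inference network around
    a shared convolutional encoder/decoder with partial skip
    connections, and is trained with an edge-aware weighted
    reconstruction loss plus a KL term between the inferred posterior
    and the learned conditional prior.  Includes a synthetic osteolysis
    phantom simulator for longitudinal bone cross-sections, image-stack
    input/output (multi-page TIFF and NIfTI), training augmentations,
    per-pixel uncertainty maps over sampled predictions, and PSNR/SSIM
    evaluation.  All network computation (2D and 3D convolutions,
    LSTMs, reparameterized sampling, Adam) is implemented in base R
    matrix algebra with exact analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tiff,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
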