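Package: octanomaly
Title: Unsupervised Anomaly Detection for OCTA En Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised anomaly detection and localisation for optical
    coherence tomography angiography (OCTA) en face projections. Implements
    a vector-quantized variational autoencoder (VQ-VAE) with an
    autoregressive prior over its discrete latent space for scan-wise and
    pixel-wise anomaly scoring, and a Bayesian U-Net whose Monte-Carlo
    dropout epistemic uncertainty yields anomaly segmentations. Both models
    are trained on healthy images only. A seeded synthetic vessel-phantom
    generator with ground-truth vessel and anomaly masks makes every stage
    trainable and testable at desk scale, and a Hessian-eigenvalue
    vesselness filter, segmentation post-processing and scan-wise /
    pixel-wise evaluation metrics complete the pipeline. The convolutional
    network core (convolutions, batch normalisation, dropout, pooling,
    transpose convolutions, Adam) is implemented in the package with
    RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    igraph,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
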