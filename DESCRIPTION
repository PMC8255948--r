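Package: gctrecon
Title: PET-Enabled Dual-Energy CT via Kernel MLAA Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates time-of-flight PET emission data from a procedural 2D
    chest phantom and reconstructs the 511 keV gamma-ray CT (GCT) attenuation
    image by maximum-likelihood attenuation and activity (MLAA) estimation,
    including kernel-guided variants in which the attenuation image is
    represented as mu = K alpha with a k-nearest-neighbour Gaussian kernel
    matrix built from an X-ray CT prior. Kernel features may be raw image
    patches or penultimate-layer activations of a convolutional autoencoder
    (RED-CNN or Unet style) trained unsupervised on the single prior image.
    The reconstructed GCT is paired with the low-energy X-ray CT for
    constrained dual-energy multi-material decomposition into air, soft
    tissue and bone fractions, and evaluated by image mean squared error in
    dB and ensemble bias versus standard deviation over noise realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
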