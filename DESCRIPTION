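Package: damlm
Title: Domain-Adaptive Learning for Multi-Center 3D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a domain-adaptive hybrid 3D
    CNN-transformer model for multi-sequence brain MRI classification and
    tumor segmentation. Provides a synthetic multi-domain brain phantom
    generator with perturbation and scanner-profile operators, the standard
    MRI preprocessing pipeline (z-score normalization, bias-field correction,
    skull stripping, isotropic resampling, affine alignment, patch
    extraction), a trilevel domain-adaptation objective (adversarial
    confusion, cross-domain contrastive regularization, covariance
    alignment), an AdamW/cosine-decay trainer with mixed-domain batches and
    early stopping, and an evaluation harness covering classification and
    overlap metrics, cross-domain transfer, perturbation robustness,
    scanner-shift displacement, and multi-seed stability. All forward and
    backward passes are implemented in R on top of a small reverse-mode
    automatic-differentiation tape, so the full pipeline runs on a single
    CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
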