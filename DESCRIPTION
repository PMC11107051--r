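Package: hcadan
Title: Hierarchical Class-Aware Adversarial Domain Adaptation for
    Anisotropic 3D Tumor Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-center 3D tumor segmentation for anisotropic CT volumes.
    Implements the AsTr backbone (anisotropic convolution blocks,
    squeeze-and-excitation residual blocks, a multi-scale deformable
    transformer context encoder and pyramid boundary-aware decoding) together
    with hierarchical class-aware adversarial domain alignment (HCADA):
    per-scale U-Net domain discriminators trained with a least-squares
    adversarial objective, gated by a voxel-wise class attention map.
    Includes NIfTI input/output, percentile clipping and spline resampling,
    anisotropic patch extraction and augmentation, synthetic anisotropic
    phantom generation with controllable inter-domain shifts, overlap and
    surface-distance segmentation metrics, and in-center five-fold group
    cross-validation and leave-one-center-out evaluation protocols. The
    network and its training are built on a compact tape-based reverse-mode
    automatic differentiation engine with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
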