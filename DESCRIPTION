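Package: BoneBEM
Title: Binary-Prediction-Enhanced Multi-Class Inference for Distinct Bone
    Segmentation from CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for distinct bone segmentation from 3D computed tomography.
    Implements binary-prediction-enhanced multi-class (BEM) inference, in which
    a binary bone-tissue/background mask guides the voxelwise argmax over
    foreground bone classes, together with the surrounding pipeline: a 3D U-Net
    family with dual segmentation heads (trained natively, patchwise, with a
    combined cross-entropy and soft-Dice loss), sliding-window volumetric
    prediction, connected-component label correction that reassigns stray
    fragments to adjacent anchor components, per-class Sorensen-Dice evaluation
    with percentile summaries and confusion matrices, and a procedural
    generator of synthetic skeletal CT phantoms with voxelwise multi-class
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
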