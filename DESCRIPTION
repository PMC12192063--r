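Package: distillseg
Title: Collaborative-Competitive Knowledge Distillation for Single-Modality Brain Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a single-modality MRI brain-tumor segmentation network by
    distilling from a frozen full-modality teacher blended with a trainable
    peripheral-vision assistant. The teacher fuses paired modality streams with
    content-guided attention, enhances them with a multihead mixture of
    convolutional experts, and segments with a U-Net; the student competes with
    the teacher-assistant through a reward-weighted competitive loss. Includes a
    synthetic multimodal phantom generator with nested tumor labels, BraTS-style
    NIfTI slice loading, Dice evaluation over whole tumor, tumor core and
    enhancing tumor regions, and a compact CPU neural-network core with
    hand-derived backpropagation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
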