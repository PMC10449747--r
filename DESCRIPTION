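Package: alseg
Title: Active Learning for Medical Image Segmentation with Dice-Threshold
    Label Substitution and Reference-Free Quality Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale framework for training 3-D medical image
    segmentation models with staged active learning. Cases whose predicted
    segmentations score above a Dice threshold against ground truth (oracle
    mode), or are triaged as acceptable by a reference-free quality
    classifier (triage mode), re-enter training with the model's own
    prediction as the label; all other cases keep their expert ground
    truth, so the fraction of cases needing manual annotation can be
    measured. Includes NIfTI case handling, dataset-level maximum intensity
    projection cropping and percentile normalization, segmentation metrics
    (Dice, Jaccard, sensitivity, positive predictive value, modified
    Hausdorff distance), a pluggable segmenter contract with a voxelwise
    logistic reference implementation, a three-class segmentation-quality
    triage model with confusion-matrix evaluation and one-vs-rest ROC/AUC,
    and a seeded generator of multi-channel brain lesion phantoms for fully
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
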