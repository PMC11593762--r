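Package: entrofuse
Title: Entropy-Weighted Ensemble Fusion for Volumetric Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for volumetric (3D) binary segmentation,
    built around the entropy weight method: per-model calibration metric
    vectors are converted to Shannon entropies, entropies to normalized
    fusion weights, and predictions are combined by voxelwise weighted
    averaging followed by thresholding. Includes the full scalar evaluation
    metric suite (Jaccard foreground/background, mean IoU, Dice, pixel
    accuracy, error rate, precision, recall, TPR, TNR, AUROC) computed from
    a single confusion-count core, slicewise CLAHE and Gaussian-blur
    preprocessing, readers and writers for TIFF stacks, slice directories
    and HDF5 volumes, and a seeded synthetic phantom generator producing
    mitochondria-like ground truth with controllable prediction
    degradations so the whole pipeline is testable without image datasets
    or trained networks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite,
    rhdf5,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
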