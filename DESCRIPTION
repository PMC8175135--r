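Package: ctnodule
Title: Thyroid Nodule Recognition and Classification in CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end recognition and benign/malignant classification of
    thyroid nodules in contrast-enhanced CT slices. A U-shaped segmentation
    network with an EfficientNet-style encoder (trained with a combined Dice
    and binary cross-entropy loss) produces per-pixel nodule probability
    maps; an image-processing connector binarizes the map, rejects noise
    blobs by area and aspect ratio, and splits it into single-nodule
    instances; a two-branch fused convolutional classifier (a shallow branch
    plus an Inception-style branch) labels each instance as benign or
    malignant with class weighting and four-view test-time augmentation.
    Includes a synthetic CT-phantom generator so every stage can be trained
    and evaluated at desk scale without patient data, plus evaluation
    metrics (IOU, Dice, accuracy, recall, precision, specificity, F1, ROC
    AUC) and overlay visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
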