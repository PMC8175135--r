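# ctnodule

End-to-end recognition and benign/malignant classification of thyroid
nodules in contrast-enhanced CT slices, for image-analysis researchers and
methodologists who need a fully inspectable, CPU-scale reference
implementation of the cascaded segmentation → instance-splitting →
classification design.

In CT, benign and malignant thyroid nodules differ mainly in *margin
morphology* (smooth versus spiculated), not gray level, so a single
multi-class segmentation network does poorly. `ctnodule` instead chains
three stages:

1. **Eff-Unet segmentation** — a U-shaped encoder–decoder with skip
   connections over an EfficientNet-style encoder (a `"tiny"` plain-conv
   encoder is provided for CPU runs), ending in a sigmoid that emits a
   per-pixel nodule probability map. Training minimizes Dice loss plus
   binary cross-entropy:

   Dice(X, Y) = (2·Σᵢxᵢyᵢ + s) / (Σᵢxᵢ + Σᵢyᵢ + s),
   L = (1 − Dice) − (1/N)·Σᵢ[xᵢ log yᵢ + (1 − xᵢ) log(1 − yᵢ)]

   with Adam (lr 0.001) and plateau-triggered halving of the learning rate.
2. **Connector** — binarize the probability map at 0.3, reject blobs by
   minimum area and maximum bounding-box aspect ratio, split the rest into
   8-connected components, and lay each nodule on a full-size black canvas
   at its original position. Reference labels come from the 0/1/2
   ground-truth mask by the mean-pixel rule (≥ 1.5 → malignant).
3. **CNN-F classification** — a shallow 3-stage conv branch (CNN-1) fused
   with an Inception-style branch (CNN-2: parallel 1×1/3×3/pooled paths,
   global average pooling, 128-node dense); features are concatenated into
   a 256-node merge and one sigmoid unit. Training uses weighted BCE
   (benign:malignant 1:3); prediction averages four dihedral views
   (test-time augmentation).

Evaluation reports IOU (Jaccard), accuracy, recall, precision,
specificity, F1 and ROC AUC with malignant as the positive class, plus an
RGB overlay (blue contours benign, red malignant).

Because annotated thyroid CT is not redistributable, the package includes
a synthetic phantom generator whose *only* class signal is margin
morphology (smooth ellipses versus spiculated boundaries), so the whole
pipeline is trainable and testable at desk scale. The entire CNN engine —
layers, reverse-mode gradients, Adam — is implemented in the package with
C++ kernels and is verified against finite differences in the tests.

## Worked example

Train tiny networks on synthetic phantoms and evaluate the assembled
pipeline on 50 held-out phantoms (about four minutes on one CPU):

```r
library(ctnodule)
study <- run_phantom_study(seed = 1, verbose = TRUE)
print(study$evaluation)
```

```
End-to-end pipeline evaluation
  nodules: 74 truth, 74 detected (IOU >= match cut), 0 false
  mean matched-nodule IOU: 0.9339   mean image IOU: 0.9419
Evaluation report (positive = malignant)
confusion counts (positive = malignant): TP 35  TN 33  FP 4  FN 2 
  accuracy     0.9189
  recall       0.9459
  precision    0.8974
  specificity  0.8919
  f1           0.9211
  auc          0.9525
  iou          0.9339
```

Reading the output: all 74 planted nodules were detected with no false
detections (a predicted instance matched each ground-truth nodule with
IOU ≥ 0.5), the matched instances overlap their nodules at mean IOU 0.93,
and the per-nodule benign/malignant calls are right for 68 of 74 matched
instances (accuracy 0.92, AUC 0.95). Missed and spurious detections, when
they occur, are reported as counts, not hidden in the confusion matrix.

Single-image use:

```r
cfg <- pipeline_config(study$seg, study$clf)
ph  <- generate_phantom(phantom_spec(image_size = 64, n_nodules = 2,
                                     nodule_radius_range = c(4, 9), seed = 99))
res <- run_end_to_end(ph$image, cfg)
print(res)                                   # per-nodule labels and probabilities
png::writePNG(res$overlay, "overlay.png")    # blue = benign, red = malignant
```

A thin CLI wrapping the same functions lives in `inst/cli/ctnodule.R`
(`generate`, `train-seg`, `train-clf`, `predict`, `evaluate`).

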