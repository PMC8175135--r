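---
title: "Recognizing and classifying thyroid nodules in CT slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and classifying thyroid nodules in CT slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Thyroid nodules are common incidental findings on contrast-enhanced CT, and
the clinically decisive question — benign or malignant — shows up in CT
mostly as a difference of *shape and margin*, not of gray level: malignant
nodules tend to have irregular, spiculated boundaries while benign nodules
present smooth, near-convex margins. A single multi-class segmentation
network that tries to separate background / benign / malignant in one shot
performs poorly precisely because the class signal is morphological rather
than photometric. `ctnodule` therefore decomposes the task into three
cooperating stages:

1. **Segmentation.** A U-shaped encoder–decoder network with skip
   connections maps a grayscale slice to a per-pixel nodule probability
   map. The encoder can be a plain small convolutional stack (`"tiny"`,
   < 100k parameters, trainable on one CPU) or an EfficientNet-style stack
   of inverted-bottleneck blocks (1×1 expansion, depthwise 3×3, 1×1
   projection, swish activations, residual adds) selected by backbone name.
   Ground-truth masks use the convention 0 = background, 1 = benign,
   2 = malignant; before segmentation training the mask is collapsed to
   binary (`min(mask, 1)`), because this stage only separates nodule from
   background.
2. **Connector.** The probability map is binarized at a permissive
   threshold (0.3), small blobs and elongated streaks are rejected by area
   and bounding-box aspect-ratio filters, and each remaining 8-connected
   component becomes one nodule instance laid on a full-size black canvas
   at its original position. Each instance's reference label is read off
   the ground-truth mask as the mean pixel value under the canvas: below
   1.5 benign, at or above 1.5 malignant.
3. **Classification.** A two-branch fused network (CNN-F) scores each
   instance: a shallow branch of three conv/max-pool stages captures
   low-level edge and shape cues; a deeper Inception-style branch (parallel
   1×1 / 3×3 / pooled-projection paths, concatenated; global average
   pooling; a 128-node dense layer) captures higher-level structure. The
   two feature vectors are concatenated, merged through a 256-node dense
   layer, and a single sigmoid unit emits the malignancy probability.
   Prediction averages four dihedral views (identity, horizontal mirror,
   vertical mirror, 180° rotation) — test-time augmentation without any
   interpolation artifacts.

## Objectives and training

The segmentation objective is the sum of soft Dice loss and binary
cross-entropy. Writing \(X\) for the truth mask and \(Y\) for the predicted
probabilities,

\[
\mathrm{Dice}(X, Y) = \frac{2\sum_i x_i y_i + s}{\sum_i x_i + \sum_i y_i + s},
\qquad
\mathcal{L} = \bigl(1 - \mathrm{Dice}\bigr) \;-\;
\frac{1}{N}\sum_i \bigl[x_i \log y_i + (1 - x_i)\log(1 - y_i)\bigr].
\]

Dice optimizes the evaluation criterion directly and is robust to the
extreme foreground/background imbalance of nodule masks; the cross-entropy
term stabilizes its gradients early in training. The smoothing constant
\(s\) defaults to 1 (so two empty masks compare as identical); `smooth = 0`
recovers the exact set formula, which is what the unit tests assert against
brute-force pixel counting. Term weights are exposed and default to 1:1.

The classifier trains on weighted binary cross-entropy with class weights
benign:malignant = 1:3, countering the roughly 3:1 benign excess seen in
clinical series; the weighted batch loss is the mean over samples of
(weight × per-sample BCE). Both networks use Adam at learning rate 0.001
with plateau-triggered decay: when the epoch loss has not improved for
`lr_patience` epochs (default 10) the rate is multiplied by `lr_factor`
(0.5), then held for `lr_cooldown` epochs (10). Defaults mirror a
ReduceLROnPlateau schedule; production-scale runs would use 200 epochs,
while the built-in study uses far fewer (below).

All layers, the reverse-mode gradients and the Adam update are implemented
in the package itself over dense R arrays with C++ kernels for convolution
and pooling; there is no batch normalization (the tiny networks train
stably without it, and omitting it keeps runs bit-reproducible for a fixed
seed). Gradients are verified against central finite differences in the
test suite (relative error below 1e-4 on toy networks; in practice ~1e-8).
No pretrained weights ship with the package, so `pretrained = TRUE` in
either model configuration is an error rather than a silent fallback.

## The phantom generator

Real annotated thyroid CT is not redistributable, so the package generates
synthetic phantoms that preserve exactly the properties the pipeline
depends on, and nothing else:

* a low-contrast soft-tissue background: base level 0.32, a random
  low-frequency gradient, smoothed structural noise, and per-pixel noise
  (`background_noise_sigma`, default 0.02);
* 1–3 non-overlapping nodules per image, intensity-offset from the
  background by `nodule_contrast` (default 0.35) so they are segmentable;
* class-dependent morphology as the *only* class signal: benign nodules
  are ellipses with a fixed tiny boundary modulation (amplitude 0.03),
  malignant nodules modulate the ellipse radius with a random harmonic
  series of 5–12 lobes at `spiculation_amplitude` (default 0.4). Shapes
  are star-convex by construction, so every nodule is one connected
  component.

Radius and center are rejection-sampled together until all nodules are
pairwise disjoint; a placement that cannot be satisfied within the retry
budget raises an error naming the spec. Masks use the 0/1/2 convention
with literal byte values in the PNGs. The generator makes no attempt at
radiological realism — no Hounsfield calibration, no scanner artifacts, no
anatomy. Consequently, passing the phantom study shows that the *pipeline
mechanics* (losses, connector, fusion, TTA, evaluation) work and that the
networks can learn a morphology-only discrimination; it says nothing about
accuracy on real patients.

## Numerical and design choices

* **Binarization threshold 0.3, ties to foreground.** A permissive cut
  keeps faint nodules; the noise filters remove what it lets through.
  Probabilities exactly at the threshold count as foreground.
* **Noise filter defaults** `min_area = 10` px, `max_aspect_ratio = 4`:
  small enough to keep genuine small nodules, strict enough to drop
  speckle and streak artifacts. Both are configuration knobs.
* **8-connectivity** for components, so diagonal necks do not split a
  nodule in two.
* **Reference-label midpoint 1.5, ties malignant** — the clinically
  conservative direction.
* **Classifier input: dilated masked grayscale.** The nodule's original
  intensities on a black canvas, with the component dilated by a disc of
  `crop_margin` pixels (default 4) before masking. Strict masking was
  tried first and failed: a segmentation network reproduces a nodule's
  gross extent but rounds off its spiculated margin, and cutting
  intensities at that smoothed boundary removes the very morphology the
  classifier needs (held-out accuracy fell to chance). Keeping a thin band
  of context restores the margin signal (held-out accuracy ≈ 0.85 in the
  built-in study). `crop_margin = 0` restores strict masking.
* **Classifier training crops come from the segmentation output**, cut by
  the same connector used at prediction time, with labels read off the
  truth mask. Training on truth-shaped crops and predicting on
  network-shaped crops is a domain shift that measurably destroys recall.
* **The segmenter must be trained to high boundary fidelity before the
  classifier can work.** At training IOU around 0.85 the predicted
  components are smoothed ellipses whose shape carries *no* class
  information (the rank AUC of a simple boundary-roughness statistic on
  predicted canvases drops to ~0.5, against 1.0 on ground-truth
  canvases); pushed to training IOU ≈ 0.99 the predicted boundary
  reproduces spiculation and the same statistic reaches AUC ≈ 0.99. The
  built-in study therefore trains the segmenter well past the point of
  "good enough IOU".
* **TTA rotation = 180°**: shape-preserving, interpolation-free; the view
  set forms the dihedral group that the training-time crop augmentation
  (`augment_crops_4view`) also uses.
* **Decision threshold 0.5** on the averaged sigmoid output.
* **Evaluation matching**: predicted instances match ground-truth nodules
  one-to-one, greedily by descending canvas IOU, requiring IOU ≥ 0.5;
  confusion counts (malignant = positive), ROC AUC (rank statistic, ties
  half) and per-nodule IOU are computed over matched pairs, and unmatched
  instances are reported as missed/false detections. Undefined statistics
  (zero denominators) are flagged `NA`, never 0. Image-level IOU is
  macro-averaged (mean of per-image IOU).

## The built-in study and its problem sizes

`run_phantom_study()` is the package's end-to-end self-test, sized for a
single CPU: 64×64 phantoms with 1–2 nodules of radius 4–9 px (easy
contrast 0.4, noise 0.01); a tiny-backbone segmentation network trained on
20 phantoms for 90 epochs; classifier crops harvested from 70 phantoms
through the trained segmenter, expanded four-fold by dihedral views, and
used to train the tiny CNN-F for 35 epochs; evaluation on 50 held-out
phantoms. All sub-seeds derive from one master seed, and the whole study
is deterministic given it. Typical results across master seeds: image-level
IOU ≈ 0.88–0.94, detection rate ≈ 0.99, classification accuracy ≈
0.92–1.0, AUC ≈ 0.95–1.0 (the acceptance script and test suite recompute
these; nothing here is asserted beyond what they measure).

## Known limitations

* The engine is CPU-bound and dense; it is sized for the tiny and
  mini configurations. The EfficientNet-style presets (b0–b4) build and
  train correctly but are not practical at 256×256 on one CPU.
* Phantom realism is deliberately minimal (see above); thresholds tuned on
  phantoms (noise filters, crop margin) would need re-examination on real
  CT.
* The classifier sees one slice; no 3-D aggregation across slices.
* DICOM ingestion, windowing and annotation tooling are out of scope; the
  package consumes 8-bit PNG/JPEG rasters.
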