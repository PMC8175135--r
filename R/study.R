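#' Desk-scale phantom study: train tiny networks and evaluate end to end
#'
#' Runs the whole pipeline at CPU scale on synthetic phantoms: trains a
#' tiny-backbone U-shaped segmentation network on easy phantoms, harvests
#' ground-truth nodule crops to train the tiny fused classifier (with
#' four-view flip/rotation augmentation of the training crops), then
#' evaluates the assembled pipeline on held-out phantoms. This is the
#' package's built-in self-test of the end-to-end method; every quantity it
#' reports is computed at run time.
#'
#' The phantom protocol: 64 x 64 images, 1-2 nodules of base radius 4-9 px,
#' benign fraction 0.5, malignant spiculation amplitude 0.4 versus smooth
#' benign margins, nodule/background contrast 0.4, background noise 0.01.
#'
#' @param seed master seed; all sub-seeds derive from it.
#' @param n_train_seg phantoms for segmentation training.
#' @param n_train_clf phantoms harvested for classifier training crops.
#' @param n_test held-out phantoms for the end-to-end evaluation.
#' @param seg_epochs,clf_epochs training epochs for the two networks.
#' @param image_size phantom side length in pixels.
#' @param verbose print stage progress.
#' @return A list with the trained \code{seg} and \code{clf} models, the
#'   [evaluate_pipeline()] result (\code{evaluation}) and the phantom spec
#'   used (\code{spec}).
#' @export
run_phantom_study <- function(seed = 1L, n_train_seg = 20L,
                              n_train_clf = 70L, n_test = 50L,
                              seg_epochs = 90L, clf_epochs = 35L,
                              image_size = 64L, verbose = FALSE) {
  seed <- as.integer(seed)
  set.seed(seed)  # every stage re-seeds, but pin the ambient state too
  say <- function(...) if (verbose) message(...)
  spec <- phantom_spec(image_size = image_size, n_nodules = c(1L, 2L),
                       nodule_radius_range = c(4, 9), benign_fraction = 0.5,
                       spiculation_amplitude = 0.4,
                       background_noise_sigma = 0.01, nodule_contrast = 0.4)
  mk <- function(n, block) lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- (seed + 1009L * block + 104729L * i) %% 2147483647L
    generate_phantom(sp)
  })

  say("training segmentation network (", n_train_seg, " phantoms, ",
      seg_epochs, " epochs)")
  seg <- build_eff_unet(
    seg_model_config(backbone = "tiny", input_size = image_size,
                     encoder_depth = 3L),
    seed = seed)
  seg <- train_segmentation(seg, mk(n_train_seg, 1L),
                            seg_train_config(epochs = seg_epochs,
                                             batch_size = 8L, seed = seed))

  # Classifier crops come from the segmentation output run through the
  # connector (not from the ground-truth masks), so the classifier trains
  # on the same boundary statistics it will see at prediction time; the
  # reference labels still come off the truth mask via the mean-pixel rule.
  say("harvesting classifier training crops (", n_train_clf, " phantoms)")
  crops <- harvest_nodule_crops(mk(n_train_clf, 2L), seg = seg)
  crops <- augment_crops_4view(crops)

  say("training classifier (", length(crops), " crops, ", clf_epochs,
      " epochs)")
  clf <- build_cnnf(cfg = clf_model_config_tiny(image_size), seed = seed)
  clf <- train_classifier(clf, crops,
                          clf_train_config(epochs = clf_epochs,
                                           batch_size = 16L, seed = seed))

  say("evaluating end to end (", n_test, " held-out phantoms)")
  cfg <- pipeline_config(seg, clf)
  evaluation <- evaluate_pipeline(mk(n_test, 3L), cfg)
  list(seg = seg, clf = clf, evaluation = evaluation, spec = spec)
}

#' Harvest labeled nodule crops from image/mask records
#'
#' Splits a nodule mask into instances and pairs each masked grayscale
#' canvas (intensities inside the nodule, zero outside) with the reference
#' label read off the 0/1/2 ground-truth mask via the mean-pixel rule. By
#' default the ground-truth mask itself is split; when a trained
#' segmentation model is supplied, instances are instead cut from its
#' predicted mask run through the connector (binarize, noise-filter,
#' split), so downstream training sees prediction-shaped boundaries.
#'
#' @param dataset list of records with \code{image} and \code{mask}.
#' @param seg optional trained segmentation model.
#' @return List of \code{list(x, y)} training records (y: 0 benign,
#'   1 malignant).
#' @export
#' @param crop_margin disc-dilation radius applied to each instance canvas
#'   before masking, as in [pipeline_config()]; keep it equal to the
#'   pipeline's value so training and prediction crops share the same
#'   statistics.
harvest_nodule_crops <- function(dataset, seg = NULL, crop_margin = 4L) {
  out <- list()
  for (d in dataset) {
    bin <- if (is.null(seg)) binarize_mask_for_segmentation(d$mask)
      else filter_noise(binarize_prediction(predict_mask(seg, d$image)))
    for (inst in split_nodules(bin)) {
      lab <- assign_reference_label(inst, d$mask)
      crop <- d$image * dilate_canvas(inst$canvas, crop_margin)
      out[[length(out) + 1L]] <- list(x = crop,
                                      y = as.numeric(lab == "malignant"))
    }
  }
  out
}

#' Expand crops with the four dihedral views used at test time
#'
#' Identity, horizontal mirror, vertical mirror and 180-degree rotation —
#' the same view set as [predict_tta()], applied at training time.
#'
#' @param crops list of \code{list(x, y)} records.
#' @return The four-fold expanded list.
#' @export
augment_crops_4view <- function(crops) {
  out <- vector("list", 4L * length(crops))
  k <- 0L
  for (r in crops) {
    for (v in 1:4) {
      x <- r$x
      if (v %in% c(2, 4)) x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
      if (v %in% c(3, 4)) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]
      k <- k + 1L
      out[[k]] <- list(x = x, y = r$y)
    }
  }
  out
}
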