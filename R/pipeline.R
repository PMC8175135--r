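# End-to-end orchestration: probability mask -> binarization -> noise
# filtering -> instance splitting -> per-nodule classification -> overlay.

#' Pipeline configuration
#'
#' @param seg_model segmentation model object or checkpoint path.
#' @param clf_model classifier model object or checkpoint path.
#' @param threshold binarization cut for the probability mask.
#' @param min_area,max_aspect_ratio noise-filter parameters, see
#'   [filter_noise()].
#' @param tta whether to classify with four-view test-time augmentation.
#' @param crop_margin pixels of disc dilation applied to an instance's
#'   canvas before masking the grayscale crop handed to the classifier.
#'   The predicted component rounds off the lesion margin, and the margin
#'   carries the benign/malignant morphology, so a small band of context
#'   (default 4 px) is kept around the component; 0 masks strictly.
#' @param match_iou minimum instance IOU for a predicted nodule to count as
#'   a detection of a ground-truth nodule during evaluation.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seg_model, clf_model, threshold = 0.3,
                            min_area = 10L, max_aspect_ratio = 4.0,
                            tta = TRUE, crop_margin = 4L, match_iou = 0.5) {
  if (is.character(seg_model)) seg_model <- load_model(seg_model)
  if (is.character(clf_model)) clf_model <- load_model(clf_model)
  if (!is.function(seg_model) && !is.function(clf_model) &&
      !is.null(seg_model$cfg$input_size) &&
      !is.null(clf_model$cfg$input_size) &&
      seg_model$cfg$input_size != clf_model$cfg$input_size)
    stop("segmentation and classifier input sizes are incompatible")
  structure(list(seg_model = seg_model, clf_model = clf_model,
                 threshold = threshold, min_area = min_area,
                 max_aspect_ratio = max_aspect_ratio, tta = isTRUE(tta),
                 crop_margin = as.integer(crop_margin),
                 match_iou = match_iou),
            class = "pipeline_config")
}

# Boundary pixels of a binary canvas: foreground with at least one
# 4-neighbor of background (image border counts as background).
canvas_boundary <- function(canvas) {
  H <- nrow(canvas); W <- ncol(canvas)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- canvas
  inner <- pad[2:(H + 1L), 2:(W + 1L)] == 1L
  nb <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  inner & !nb
}

#' Run the full recognition and classification pipeline on one image
#'
#' Applies, in order: segmentation ([predict_mask()]), binarization
#' ([binarize_prediction()]), noise filtering ([filter_noise()]), instance
#' splitting ([split_nodules()]) and per-nodule classification
#' ([predict_tta()]). The classifier input is the masked grayscale nodule
#' on the full-size canvas: original intensities inside the component
#' (dilated by \code{cfg$crop_margin} pixels to keep the lesion margin),
#' zero outside. An image may legitimately yield zero nodules.
#'
#' @param image numeric matrix in \code{[0, 1]}.
#' @param cfg a [pipeline_config()].
#' @return An object of class \code{pipeline_result}: \code{instances}
#'   (each with \code{pred_label} / \code{pred_prob} filled in),
#'   \code{results} (per-instance [predict_tta()] outputs),
#'   \code{prob_mask}, \code{binary_mask} and \code{overlay} (H x W x 3 RGB
#'   array; benign contours blue, malignant red).
#' @export
run_end_to_end <- function(image, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  prob <- predict_mask(cfg$seg_model, image)
  bin <- binarize_prediction(prob, cfg$threshold)
  bin <- filter_noise(bin, cfg$min_area, cfg$max_aspect_ratio)
  instances <- split_nodules(bin)

  overlay <- array(rep(pmin(pmax(image, 0), 1), 3L), c(dim(image), 3L))
  results <- vector("list", length(instances))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    crop <- image * dilate_canvas(inst$canvas, cfg$crop_margin)
    res <- predict_tta(cfg$clf_model, crop, tta = cfg$tta)
    inst$pred_label <- res$pred_label
    inst$pred_prob <- res$pred_prob
    instances[[i]] <- inst
    results[[i]] <- res
    edge <- canvas_boundary(inst$canvas)
    col <- if (res$pred_label == "benign") c(0, 0, 1) else c(1, 0, 0)
    for (ch in 1:3) {
      plane <- overlay[, , ch]
      plane[edge] <- col[ch]
      overlay[, , ch] <- plane
    }
  }
  structure(list(instances = instances, results = results,
                 prob_mask = prob, binary_mask = bin, overlay = overlay),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:", length(x$instances), "nodule(s) detected\n")
  for (inst in x$instances)
    cat(sprintf("  %s (p = %.3f), area %d px, bbox rows [%d,%d)\n",
                inst$pred_label, inst$pred_prob, inst$area,
                inst$bbox["row_min"], inst$bbox["row_max"]))
  invisible(x)
}

# Greedy one-to-one matching of predicted to truth instances by descending
# pairwise canvas IOU; pairs below `min_iou` never match.
match_instances <- function(pred, truth, min_iou = 0.5) {
  if (!length(pred) || !length(truth))
    return(list(pairs = matrix(integer(0), 0, 2), ious = numeric(0)))
  M <- outer(seq_along(pred), seq_along(truth),
             Vectorize(function(i, j) iou(pred[[i]]$canvas,
                                          truth[[j]]$canvas)))
  pairs <- NULL; ious <- numeric(0)
  repeat {
    best <- which(M == max(M), arr.ind = TRUE)[1, , drop = FALSE]
    if (M[best] < min_iou) break
    pairs <- rbind(pairs, best)
    ious <- c(ious, M[best])
    M[best[1], ] <- -1
    M[, best[2]] <- -1
    if (all(M < min_iou)) break
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  list(pairs = pairs, ious = ious)
}

#' Evaluate the end-to-end pipeline on a labeled dataset
#'
#' For each image, ground-truth instances are derived by splitting the
#' binarized truth mask and reading their labels off the 0/1/2 mask;
#' predicted instances come from [run_end_to_end()]. Predictions are
#' matched one-to-one to truth nodules greedily by descending canvas IOU
#' (a match requires IOU >= \code{cfg$match_iou}). Confusion counts are
#' built over the matched pairs' labels; unmatched truth nodules are missed
#' detections and unmatched predictions false detections, reported as
#' counts.
#'
#' @param dataset a dataset directory (see [generate_dataset()]) or a list
#'   of records with \code{image} and \code{mask}.
#' @param cfg a [pipeline_config()].
#' @return An object of class \code{pipeline_evaluation}: a
#'   \code{metrics_report} (accuracy, recall, precision, specificity, F1,
#'   AUC over matched instances; \code{iou} = mean matched-nodule IOU) plus
#'   \code{mean_image_iou} (whole-image segmentation IOU), and detection
#'   counts.
#' @export
evaluate_pipeline <- function(dataset, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  if (!length(dataset)) stop("empty evaluation dataset")
  pred_labels <- character(0); true_labels <- character(0)
  probs <- numeric(0); matched_ious <- numeric(0)
  image_ious <- numeric(0)
  n_truth <- 0L; n_pred <- 0L; n_matched <- 0L
  for (rec in dataset) {
    if (is.null(rec$mask)) stop("dataset record is missing a mask")
    truth_bin <- binarize_mask_for_segmentation(rec$mask)
    truth_inst <- split_nodules(truth_bin)
    for (i in seq_along(truth_inst))
      truth_inst[[i]]$ref_label <-
        assign_reference_label(truth_inst[[i]], rec$mask)
    out <- run_end_to_end(rec$image, cfg)
    image_ious <- c(image_ious, iou(out$binary_mask, truth_bin))
    mm <- match_instances(out$instances, truth_inst, cfg$match_iou)
    n_truth <- n_truth + length(truth_inst)
    n_pred <- n_pred + length(out$instances)
    n_matched <- n_matched + nrow(mm$pairs)
    matched_ious <- c(matched_ious, mm$ious)
    if (nrow(mm$pairs)) {
      pred_labels <- c(pred_labels, vapply(
        mm$pairs[, 1], function(i) out$instances[[i]]$pred_label, ""))
      true_labels <- c(true_labels, vapply(
        mm$pairs[, 2], function(j) truth_inst[[j]]$ref_label, ""))
      probs <- c(probs, vapply(
        mm$pairs[, 1], function(i) out$instances[[i]]$pred_prob, 0))
    }
  }
  report <- classification_metrics(confusion(pred_labels, true_labels))
  report$auc <- as.numeric(roc_auc(probs, true_labels))
  report$iou <- if (length(matched_ious)) mean(matched_ious) else NA_real_
  structure(list(report = report,
                 mean_matched_iou = report$iou,
                 mean_image_iou = mean(image_ious),
                 n_truth = n_truth, n_detected = n_matched,
                 n_false_detections = n_pred - n_matched),
            class = "pipeline_evaluation")
}

#' @export
print.pipeline_evaluation <- function(x, ...) {
  cat("End-to-end pipeline evaluation\n")
  cat(sprintf("  nodules: %d truth, %d detected (IOU >= match cut), %d false\n",
              x$n_truth, x$n_detected, x$n_false_detections))
  cat(sprintf("  mean matched-nodule IOU: %s   mean image IOU: %.4f\n",
              ifelse(is.na(x$mean_matched_iou), "undefined",
                     sprintf("%.4f", x$mean_matched_iou)),
              x$mean_image_iou))
  print(x$report)
  invisible(x)
}
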