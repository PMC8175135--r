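# The connector between the segmentation and classification networks:
# threshold the probability map, drop noise blobs, split the remaining
# foreground into per-nodule instances on full-size black canvases, and
# read reference labels off the ground-truth mask.

#' Label connected components of a binary mask
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8, so diagonal necks do not split a
#'   nodule).
#' @return Integer matrix of component labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask
  storage.mode(m) <- "integer"
  cpp_label_components(m, as.integer(connectivity))
}

#' Binarize a segmentation probability map
#'
#' A pixel is foreground iff its probability is \code{>= threshold} (ties at
#' the threshold map to foreground). The working default of 0.3 deliberately
#' sits below one half: the segmentation network is trained on scarce
#' foreground, and a permissive cut keeps faint nodules that the later area
#' and aspect-ratio filters can still reject.
#'
#' @param prob numeric matrix of probabilities in \code{[0, 1]}.
#' @param threshold cut point, strictly inside \code{(0, 1)}.
#' @return Integer matrix in \{0, 1\}.
#' @export
binarize_prediction <- function(prob, threshold = 0.3) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  if (min(prob) < 0 || max(prob) > 1)
    stop("probability map has values outside [0, 1]")
  out <- (prob >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

component_stats <- function(lab) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    h <- diff(range(idx[, 1])) + 1L
    w <- diff(range(idx[, 2])) + 1L
    list(id = id, area = nrow(idx),
         row_min = min(idx[, 1]), row_max = max(idx[, 1]),
         col_min = min(idx[, 2]), col_max = max(idx[, 2]),
         aspect_ratio = max(h, w) / min(h, w))
  })
}

#' Remove noise blobs from a binary mask
#'
#' Every connected component with area below \code{min_area} or bounding-box
#' aspect ratio above \code{max_aspect_ratio} is erased; all surviving
#' components are returned unchanged. Idempotent.
#'
#' @param mask binary matrix.
#' @param min_area minimum component area in pixels (>= 1).
#' @param max_aspect_ratio maximum \code{max(h, w) / min(h, w)} of the
#'   component bounding box.
#' @return Filtered binary matrix.
#' @export
filter_noise <- function(mask, min_area = 10L, max_aspect_ratio = 4.0) {
  if (min_area < 1) stop("min_area must be >= 1")
  lab <- label_components(mask)
  out <- mask
  storage.mode(out) <- "integer"
  for (st in component_stats(lab))
    if (st$area < min_area || st$aspect_ratio > max_aspect_ratio)
      out[lab == st$id] <- 0L
  out
}

# Morphological dilation of a binary canvas by a disc of radius `margin`
# pixels. Used to retain a thin band of context around a nodule when its
# grayscale crop is cut out: the predicted component tends to round off the
# lesion margin, and the margin is where the diagnostic morphology lives.
dilate_canvas <- function(canvas, margin) {
  if (margin <= 0) return(canvas)
  out <- round(as.matrix(EBImage::dilate(
    canvas, EBImage::makeBrush(2L * as.integer(margin) + 1L, "disc"))))
  storage.mode(out) <- "integer"
  out
}

new_nodule_instance <- function(canvas, st) {
  structure(list(
    canvas = canvas,
    # 0-based, half-open bounding box (row_min, col_min, row_max, col_max)
    bbox = c(row_min = st$row_min - 1L, col_min = st$col_min - 1L,
             row_max = st$row_max, col_max = st$col_max),
    area = st$area, aspect_ratio = st$aspect_ratio,
    ref_label = NA_character_, pred_label = NA_character_,
    pred_prob = NA_real_), class = "nodule_instance")
}

#' @export
print.nodule_instance <- function(x, ...) {
  cat(sprintf(
    "nodule instance: area %d px, bbox [%d,%d)x[%d,%d), aspect %.2f\n",
    x$area, x$bbox["row_min"], x$bbox["row_max"], x$bbox["col_min"],
    x$bbox["col_max"], x$aspect_ratio))
  if (!is.na(x$ref_label)) cat("  reference label:", x$ref_label, "\n")
  if (!is.na(x$pred_label))
    cat(sprintf("  predicted: %s (p = %.3f)\n", x$pred_label, x$pred_prob))
  invisible(x)
}

#' Split a binary mask into single-nodule instances
#'
#' Each 8-connected component becomes one \code{nodule_instance}: a
#' full-size black canvas carrying only that component at its original
#' position, plus its bounding box (0-based, half-open), area and aspect
#' ratio. The canvases OR-combine back to the input mask. Instances are
#' ordered by (row_min, col_min).
#'
#' @param mask binary matrix, already noise-filtered.
#' @param image_size expected side length; defaults to the mask's own size.
#' @return List of \code{nodule_instance} objects (empty for an empty
#'   mask).
#' @export
split_nodules <- function(mask, image_size = nrow(mask)) {
  if (nrow(mask) != image_size || ncol(mask) != image_size)
    stop("mask is not ", image_size, "x", image_size)
  lab <- label_components(mask)
  stats <- component_stats(lab)
  inst <- lapply(stats, function(st) {
    canvas <- matrix(0L, nrow(mask), ncol(mask))
    canvas[lab == st$id] <- 1L
    new_nodule_instance(canvas, st)
  })
  ord <- order(vapply(inst, function(x) x$bbox[["row_min"]], 0L),
               vapply(inst, function(x) x$bbox[["col_min"]], 0L))
  inst[ord]
}

#' Assign a reference label to an instance from the ground-truth mask
#'
#' Averages the 0/1/2 ground-truth values under the instance's canvas and
#' returns the nearest label: benign when the mean is below 1.5, malignant
#' at or above it (ties break toward malignant).
#'
#' @param instance a \code{nodule_instance}.
#' @param truth integer matrix in \{0, 1, 2\}.
#' @return \code{"benign"} or \code{"malignant"}.
#' @export
assign_reference_label <- function(instance, truth) {
  stopifnot(inherits(instance, "nodule_instance"))
  check_mask(truth)
  sel <- instance$canvas == 1L
  if (!any(sel)) stop("instance canvas is empty")
  if (mean(truth[sel]) < 1.5) "benign" else "malignant"
}
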