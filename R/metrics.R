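# Evaluation statistics with malignant as the positive class throughout.
# Metrics whose denominator is zero are reported as flagged NA, never as 0,
# so degenerate evaluation sets stay visible in reports.

#' Confusion counts with malignant as the positive class
#'
#' @param pred_labels,true_labels equal-length character vectors with values
#'   \code{"benign"} / \code{"malignant"} (or 0/1, coerced with 1 =
#'   positive).
#' @param positive label treated as positive (default \code{"malignant"}).
#' @return An object of class \code{confusion_counts}: list with integer
#'   fields \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @export
confusion <- function(pred_labels, true_labels, positive = "malignant") {
  if (length(pred_labels) != length(true_labels))
    stop("pred_labels and true_labels differ in length")
  p <- as_positive(pred_labels, positive)
  y <- as_positive(true_labels, positive)
  structure(list(tp = sum(p & y), tn = sum(!p & !y),
                 fp = sum(p & !y), fn = sum(!p & y)),
            class = "confusion_counts")
}

as_positive <- function(x, positive) {
  if (is.character(x) || is.factor(x)) as.character(x) == positive
  else as.numeric(x) >= 0.5
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (positive = malignant): TP", x$tp, " TN", x$tn,
      " FP", x$fp, " FN", x$fn, "\n")
  invisible(x)
}

#' Classification statistics from confusion counts
#'
#' Computes accuracy \eqn{(TP+TN)/(TP+TN+FP+FN)}, recall (sensitivity)
#' \eqn{TP/(TP+FN)}, precision \eqn{TP/(TP+FP)}, specificity
#' \eqn{TN/(TN+FP)} and F1 \eqn{2 P R / (P + R)}. Any statistic with a zero
#' denominator is \code{NA} and named in the report's \code{flags}.
#'
#' @param counts a [confusion()] result.
#' @return An object of class \code{metrics_report}.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, {
    acc <- rat(tp + tn, tp + tn + fp + fn)
    rec <- rat(tp, tp + fn)
    pre <- rat(tp, tp + fp)
    spe <- rat(tn, tn + fp)
    f1 <- if (is.na(pre) || is.na(rec) || pre + rec == 0) NA_real_
      else 2 * pre * rec / (pre + rec)
    vals <- c(accuracy = acc, recall = rec, precision = pre,
              specificity = spe, f1 = f1)
    structure(list(accuracy = acc, recall = rec, precision = pre,
                   specificity = spe, f1 = f1, auc = NA_real_,
                   iou = NA_real_, counts = counts,
                   flags = names(vals)[is.na(vals)]),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("Evaluation report (positive = malignant)\n")
  print(x$counts)
  for (nm in c("accuracy", "recall", "precision", "specificity", "f1",
               "auc", "iou"))
    if (!(nm %in% c("auc", "iou")) || !is.na(x[[nm]]))
      cat(sprintf("  %-12s %s\n", nm, fmt(x[[nm]])))
  if (length(x$flags))
    cat("  flagged undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' ROC AUC by the rank statistic
#'
#' The probability that a randomly chosen positive instance scores above a
#' randomly chosen negative one, with ties counted one half — equivalently
#' the area under the empirical ROC curve.
#'
#' @param pred_probs numeric scores (higher = more malignant).
#' @param true_labels labels; see [confusion()].
#' @param positive positive-class label.
#' @return AUC in \code{[0, 1]}, or flagged \code{NA} when only one class is
#'   present.
#' @export
roc_auc <- function(pred_probs, true_labels, positive = "malignant") {
  if (length(pred_probs) != length(true_labels))
    stop("scores and labels differ in length")
  y <- as_positive(true_labels, positive)
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0)
    return(structure(NA_real_, undefined = TRUE))
  r <- rank(pred_probs)
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Intersection over union of two binary masks
#'
#' \eqn{|X \cap Y| / |X \cup Y|} with a small additive smoothing so that two
#' empty masks score 1.
#'
#' @param pred,truth binary matrices of identical shape.
#' @param smooth additive smoothing constant.
#' @return IOU in \code{[0, 1]}.
#' @export
iou <- function(pred, truth, smooth = 1e-7) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ")
  i <- sum(pred * truth)
  u <- sum(pred) + sum(truth) - i
  (i + smooth) / (u + smooth)
}

#' Mean per-image IOU over paired mask sets
#'
#' @param pred_masks,truth_masks lists of binary matrices, paired by
#'   position.
#' @return Mean of the per-image IOU values (macro average).
#' @export
evaluate_segmentation <- function(pred_masks, truth_masks) {
  if (length(pred_masks) != length(truth_masks))
    stop("prediction and truth sets differ in length")
  mean(mapply(iou, pred_masks, truth_masks))
}
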