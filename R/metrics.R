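# Pixel-level evaluation metrics for binary segmentation: Dice, mean IoU
# over {foreground, background}, recall, precision and F1. A ratio whose
# denominator is zero is defined as 1 (both masks agree the class is
# absent).

#' Pixelwise confusion counts between two binary masks
#'
#' @param y ground-truth binary mask.
#' @param pred predicted binary mask of the same shape.
#' @return named list with `tp`, `fp`, `fn`, `tn`; the four counts sum to
#'   the pixel count.
#' @export
confusionCounts <- function(y, pred) {
  if (!identical(dim(y), dim(pred)) || length(y) != length(pred)) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("confusion counts require strictly binary masks", call. = FALSE)
  }
  tp <- sum(y == 1 & pred == 1)
  fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0)
  tn <- sum(y == 0 & pred == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

safeRatio <- function(num, den) if (den == 0) 1 else num / den

#' Segmentation metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN); mean IoU averages the foreground IoU
#' TP/(TP+FN+FP) and the background IoU TN/(TN+FN+FP) (the background
#' class's true positives are the TN pixels and its errors are the same
#' complementary FP/FN pixels); recall = TP/(TP+FN); precision =
#' TP/(TP+FP); F1 is the harmonic mean of precision and recall, which for
#' binary masks is algebraically identical to Dice.
#'
#' @param counts as returned by [confusionCounts].
#' @return named numeric vector `dice, miou, recall, precision, f1`, all
#'   in `[0, 1]`.
#' @export
metricsFromCounts <- function(counts) {
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  dice <- safeRatio(2 * tp, 2 * tp + fp + fn)
  miou <- 0.5 * (safeRatio(tp, tp + fn + fp) + safeRatio(tn, tn + fn + fp))
  recall <- safeRatio(tp, tp + fn)
  precision <- safeRatio(tp, tp + fp)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(dice = dice, miou = miou, recall = recall, precision = precision,
    f1 = f1)
}

#' Metrics between a ground-truth mask and a predicted mask
#'
#' Convenience wrapper: [confusionCounts] followed by
#' [metricsFromCounts].
#'
#' @inheritParams confusionCounts
#' @return named numeric vector of the five metrics.
#' @export
segmentationMetrics <- function(y, pred) {
  metricsFromCounts(confusionCounts(y, pred))
}
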