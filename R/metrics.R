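# Pixel-level evaluation: confusion counting and the overlap metrics
# SEN = TP/(TP+FN), IOU = TP/(TP+FP+FN), DICE = 2TP/(2TP+FP+FN).

#' Pixel confusion counts
#'
#' TP is the intersection of true lesion and predicted lesion area, FP of
#' true normal and predicted lesion, TN of true normal and predicted normal,
#' FN of true lesion and predicted normal.
#'
#' @param pred,truth Binary rasters of identical shape (values 0/1 or
#'   logical).
#' @return A `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- if (inherits(pred, "lesion_mask")) pred$pixels else pred
  t <- if (inherits(truth, "lesion_mask")) truth$pixels else truth
  if (length(p) != length(t)) stop("prediction and truth shapes differ")
  if (any(p != 0 & p != 1) || any(t != 0 & t != 1))
    stop("inputs must be binary")
  p <- p == 1; t <- t == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Combine confusion counts
#'
#' Adds the four tallies; used for micro-averaged test-set scores where
#' counts are pooled over all images of a lesion class before ratios are
#' taken.
#'
#' @param ... `confusion_counts` objects.
#' @return A pooled `confusion_counts`.
#' @export
pool_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) && !inherits(cs[[1]], "confusion_counts"))
    cs <- cs[[1]]
  out <- list(tp = 0, fp = 0, tn = 0, fn = 0)
  for (c in cs) {
    stopifnot(inherits(c, "confusion_counts"))
    out$tp <- out$tp + c$tp; out$fp <- out$fp + c$fp
    out$tn <- out$tn + c$tn; out$fn <- out$fn + c$fn
  }
  structure(out, class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' Sensitivity, intersection-over-union and Dice coefficient. A metric whose
#' denominator is zero (e.g. SEN with no true lesion pixels) is reported as
#' `NA` with its `defined` flag cleared rather than silently coerced to 0
#' or 1.
#'
#' @param counts A [confusion_counts()] object.
#' @return List with numeric `sen`, `iou`, `dice` and a named logical vector
#'   `defined`.
#' @export
segmentation_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  sen_ok <- (tp + fn) > 0
  ovl_ok <- (tp + fp + fn) > 0
  list(sen = if (sen_ok) tp / (tp + fn) else NA_real_,
       iou = if (ovl_ok) tp / (tp + fp + fn) else NA_real_,
       dice = if (ovl_ok) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       defined = c(sen = sen_ok, iou = ovl_ok, dice = ovl_ok))
}

#' Evaluate a probability map against ground truth
#'
#' Thresholds the map (default 0.5) and returns counts plus scores.
#'
#' @param prob Probability raster in `[0, 1]`; `NA` pixels (uncovered by any
#'   tile) are excluded from counting.
#' @param truth Binary mask of the same shape.
#' @param threshold Decision threshold.
#' @return List with `counts` and the fields of [segmentation_scores()].
#' @export
evaluate_prediction <- function(prob, truth, threshold = 0.5) {
  t <- if (inherits(truth, "lesion_mask")) truth$pixels else truth
  if (length(prob) != length(t)) stop("shapes differ")
  keep <- !is.na(prob)
  counts <- confusion_counts(as.numeric(prob[keep] >= threshold),
                             as.numeric(t[keep]))
  c(list(counts = counts), segmentation_scores(counts))
}
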