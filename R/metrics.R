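#' Overlap metrics between a predicted and a ground-truth mask
#'
#' Standard validation of a binary segmentation against ground truth:
#' Intersection over Union `|P & T| / |P | T|`, Dice coefficient
#' `2 |P & T| / (|P| + |T|)`, and pixel accuracy `(tp + tn) / n`.  Masks are
#' binarized as nonzero = foreground.  When both masks are empty, IoU and
#' Dice are 1 by convention.
#'
#' @param pred predicted binary mask.
#' @param truth ground-truth binary mask of identical shape.
#' @return An object of class `validation_result`: `iou`, `dice`,
#'   `pixel_accuracy`, and counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' evaluate_masks(a, a)$dice  # 1
#' @export
evaluate_masks <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and ground truth must have identical shapes")
  p <- pred != 0
  t_ <- truth != 0
  tp <- sum(p & t_); fp <- sum(p & !t_)
  fn <- sum(!p & t_); tn <- sum(!p & !t_)
  union <- tp + fp + fn
  iou <- if (union == 0) 1 else tp / union
  dice <- if (tp + fp + tp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(iou = iou, dice = dice,
                 pixel_accuracy = (tp + tn) / (tp + fp + fn + tn),
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("IoU %.4f | Dice %.4f | pixel accuracy %.4f (tp %d fp %d fn %d tn %d)\n",
              x$iou, x$dice, x$pixel_accuracy, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Aggregate validation results as mean and standard deviation
#'
#' @param results nonempty list of [evaluate_masks()] results.
#' @return Data frame with one row per metric (`iou`, `dice`,
#'   `pixel_accuracy`): sample mean, sample standard deviation (n - 1
#'   denominator), and `n`.
#' @export
batch_summary <- function(results) {
  if (length(results) == 0) stop("'results' must contain at least one result")
  metrics <- c("iou", "dice", "pixel_accuracy")
  vals <- sapply(metrics, function(m) sapply(results, `[[`, m))
  vals <- matrix(vals, nrow = length(results))
  data.frame(metric = metrics,
             mean = colMeans(vals),
             sd = if (length(results) > 1) apply(vals, 2, sd) else rep(0, 3),
             n = length(results),
             row.names = NULL)
}
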