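## Pixel-level agreement between two binary masks, and cohort summaries.
##
## Conventions for degenerate denominators follow the "no finding" semantics
## of the annotation protocol: two empty masks are in perfect agreement
## (IoU = F1 = sensitivity = specificity = accuracy = 1); an empty prediction
## against a non-empty reference scores IoU = F1 = sensitivity = 0 and
## specificity = 1.

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,ref `binary_mask`s (or logical matrices) of identical size.
#' @return list with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion <- function(pred, ref) {
  p <- as_mask_matrix(pred); r <- as_mask_matrix(ref)
  check_same_dim(p, r)
  tp <- sum(p & r)
  fp <- sum(p) - tp
  fn <- sum(r) - tp
  list(tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
}

#' Intersection over union (Jaccard index) of two masks
#'
#' `tp / (tp + fp + fn)`; two empty masks score 1 (unanimous "no finding").
#'
#' @inheritParams confusion
#' @return fraction in [0, 1].
#' @export
mask_iou <- function(pred, ref) {
  cc <- confusion(pred, ref)
  denom <- cc$tp + cc$fp + cc$fn
  if (denom == 0) 1 else cc$tp / denom
}

#' F1 / Dice similarity coefficient of two masks
#'
#' `2 tp / (2 tp + fp + fn)`; two empty masks score 1. Related to IoU by
#' `f1 = 2 iou / (1 + iou)`.
#'
#' @inheritParams confusion
#' @return fraction in [0, 1].
#' @export
mask_f1 <- function(pred, ref) {
  cc <- confusion(pred, ref)
  denom <- 2 * cc$tp + cc$fp + cc$fn
  if (denom == 0) 1 else 2 * cc$tp / denom
}

#' Full agreement report between a predicted and a reference mask
#'
#' Computes IoU, F1, accuracy, sensitivity and specificity from a single
#' confusion computation.
#'
#' @inheritParams confusion
#' @return a `metric_report`: list with `iou`, `f1`, `accuracy`,
#'   `sensitivity`, `specificity` and the `counts`.
#' @export
evaluate_masks <- function(pred, ref) {
  cc <- confusion(pred, ref)
  ratio <- function(num, den, empty_value) if (den == 0) empty_value else num / den
  rep <- list(
    iou = ratio(cc$tp, cc$tp + cc$fp + cc$fn, 1),
    f1 = ratio(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn, 1),
    accuracy = (cc$tp + cc$tn) / (cc$tp + cc$fp + cc$fn + cc$tn),
    sensitivity = ratio(cc$tp, cc$tp + cc$fn, 1),   # ref empty -> nothing to find
    specificity = ratio(cc$tn, cc$tn + cc$fp, 1),   # ref full  -> nothing to reject
    counts = cc)
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("iou=%.4f f1=%.4f acc=%.4f sens=%.4f spec=%.4f\n",
              x$iou, x$f1, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

metric_names <- c("iou", "f1", "accuracy", "sensitivity", "specificity")

#' Mean and standard deviation of one metric over a cohort of reports
#'
#' Macro averaging: metrics are computed per frame and then averaged, as in
#' per-frame mean +/- sd reporting. The sd is the sample standard deviation
#' (n - 1 denominator); a single report yields sd = 0.
#'
#' @param reports list of `metric_report`s.
#' @param metric one of `iou`, `f1`, `accuracy`, `sensitivity`, `specificity`.
#' @return list with `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(reports, metric = metric_names) {
  metric <- match.arg(metric)
  if (length(reports) == 0) stop("cannot summarize an empty cohort", call. = FALSE)
  vals <- vapply(reports, function(r) r[[metric]], numeric(1))
  list(metric = metric, mean = mean(vals),
       sd = if (length(vals) > 1) stats::sd(vals) else 0,
       n = length(vals))
}
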