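# Scan-wise and pixel-wise evaluation metrics.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks score 1 by
#' convention (an anomaly-free prediction on an anomaly-free image is a
#' perfect answer, and the convention keeps test-set averages
#' meaningful).
#'
#' @param pred,gt Binary matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("mask shapes differ", call. = FALSE)
  }
  p <- pred > 0; g <- gt > 0
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

#' Intersection-over-union, sensitivity and specificity
#'
#' Confusion-matrix ratios `IoU = TP/(TP+FP+FN)`,
#' `sensitivity = TP/(TP+FN)` (true-positive rate) and
#' `specificity = TN/(TN+FP)` (true-negative rate). An empty denominator
#' scores 1 when the corresponding error count is also 0.
#'
#' @param pred,gt Binary matrices of identical shape.
#' @return Named list with `iou`, `sensitivity`, `specificity`.
#' @export
iou_sens_spec <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("mask shapes differ", call. = FALSE)
  }
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g)
  fn <- sum(!p & g); tn <- sum(!p & !g)
  safe <- function(num, den) if (den == 0) 1 else num / den
  list(iou = safe(tp, tp + fp + fn),
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp))
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen
#' positive (diseased) score exceeds a randomly chosen negative
#' (healthy) score, with ties counting one half (midrank formulation).
#'
#' @param scores Numeric vector of anomaly scores (higher = more
#'   anomalous).
#' @param labels Binary vector (1 = diseased).
#' @return A number in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  check_two_classes(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Step-wise area under the precision-recall curve:
#' `AP = sum_i (R_i - R_{i-1}) P_i` over thresholds at the distinct
#' scores in descending order (tied scores enter as one group).
#'
#' @inheritParams auroc
#' @return A number in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)   # last element of each group
  tp <- tp[last]; fp <- fp[last]
  npos <- sum(y)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' F1 score at the Youden-index operating point
#'
#' Scans all midpoints between consecutive sorted unique scores (plus
#' guards below the minimum and above the maximum), picks the threshold
#' maximising `sensitivity + specificity - 1` (Youden ties broken by
#' higher specificity, i.e. the higher threshold), and reports the F1
#' score of `score > threshold` at that operating point.
#'
#' @inheritParams auroc
#' @return A list with `f1` and `threshold`.
#' @export
f1_at_youden <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
    sens <- if (tp + fn > 0) tp / (tp + fn) else 1
    spec <- if (tn + fp > 0) tn / (tn + fp) else 1
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
      best <- list(j = j, spec = spec, f1 = f1, threshold = th)
    }
  }
  list(f1 = best$f1, threshold = best$threshold)
}

#' Scan-wise evaluation report
#'
#' @param scores Numeric anomaly scores.
#' @param labels Binary labels (1 = diseased).
#' @return A list with `auroc`, `average_precision`, `f1_at_youden`,
#'   `operating_threshold`.
#' @export
scan_eval_report <- function(scores, labels) {
  fy <- f1_at_youden(scores, labels)
  list(auroc = auroc(scores, labels),
       average_precision = average_precision(scores, labels),
       f1_at_youden = fy$f1,
       operating_threshold = fy$threshold)
}

#' Pixel-wise evaluation report over a set of images
#'
#' Per-image Dice, IoU, sensitivity and specificity plus their
#' mean +/- sd summary.
#'
#' @param preds List of binary prediction matrices.
#' @param gts List of binary ground-truth matrices.
#' @return A list with `per_image` (data.frame) and `summary`
#'   (data.frame of mean and sd per metric).
#' @export
pixel_eval_report <- function(preds, gts) {
  stopifnot(length(preds) == length(gts), length(preds) > 0)
  rows <- lapply(seq_along(preds), function(i) {
    d <- dice(preds[[i]], gts[[i]])
    m <- iou_sens_spec(preds[[i]], gts[[i]])
    data.frame(image = i, dice = d, iou = m$iou,
               sensitivity = m$sensitivity, specificity = m$specificity)
  })
  per_image <- do.call(rbind, rows)
  met <- c("dice", "iou", "sensitivity", "specificity")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(per_image[[m]]), numeric(1)),
    sd = vapply(met, function(m) stats::sd(per_image[[m]]), numeric(1)))
  list(per_image = per_image, summary = summary)
}
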