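#' Confusion counts for binary detections
#'
#' @param labels binary ground-truth vector (1 = pulse present).
#' @param predictions binary detection vector of equal length.
#' @return named list with `tp`, `fp`, `tn`, `fn`; the four counts
#'   partition the dataset.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("labels and predictions must be binary (0/1)")
  list(tp = sum(labels == 1 & predictions == 1),
       fp = sum(labels == 0 & predictions == 1),
       tn = sum(labels == 0 & predictions == 0),
       fn = sum(labels == 1 & predictions == 0))
}

#' Threshold-dependent detector metrics
#'
#' Accuracy, precision (proportion of detections that are true positives),
#' recall (proportion of true pulses detected), their harmonic mean F1, and
#' the false positive/negative rates. Ratios with zero denominators are
#' reported as `NA` with a warning rather than silently coerced to 0.
#'
#' @param confusion list with `tp`, `fp`, `tn`, `fn` as from
#'   [confusion_counts()].
#' @return named list of proportions (`accuracy`, `precision`, `recall`,
#'   `f1`, `fpr`, `fnr`) plus the four counts.
#' @export
detector_metrics <- function(confusion) {
  tp <- confusion$tp; fp <- confusion$fp
  tn <- confusion$tn; fn <- confusion$fn
  n <- tp + fp + tn + fn
  if (n <= 0) stop("empty confusion matrix")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA",
                      what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (isTRUE(!is.na(precision) && !is.na(recall) &&
             precision + recall > 0))
    2 * precision * recall / (precision + recall)
  else if (isTRUE(!is.na(precision) && !is.na(recall))) 0 else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / n,
       precision = precision, recall = recall, f1 = f1,
       fpr = ratio(fp, fp + tn, "false positive rate"),
       fnr = ratio(fn, fn + tp, "false negative rate"))
}

#' F1 score from precision and recall
#'
#' @param precision,recall proportions in \[0, 1\].
#' @return the harmonic mean `2 * p * r / (p + r)` (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' True and false positive rates at every distinct score threshold plus the
#' endpoints, with the area under the curve by the trapezoid rule (which
#' equals the pairwise probability that a positive outscores a negative,
#' counting ties as one half).
#'
#' @param labels binary ground-truth vector; both classes must be present.
#' @param scores numeric scores (higher = more pulse-like).
#' @return list with `curve` (tibble: threshold, tpr, fpr) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires both classes to be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
       auc = auc)
}

#' ROC-derived optimal threshold
#'
#' The threshold maximizing Youden's J = TPR - FPR over the ROC curve's
#' candidate thresholds; ties are broken toward 0.5.
#'
#' @param roc result of [roc_curve()] (or its `curve` tibble).
#' @return the selected finite threshold.
#' @export
optimal_threshold <- function(roc) {
  curve <- if (is.list(roc) && !is.null(roc$curve)) roc$curve else roc
  cand <- curve[is.finite(curve$threshold), , drop = FALSE]
  j <- cand$tpr - cand$fpr
  best <- which(j >= max(j) - 1e-12)
  cand$threshold[best][which.min(abs(cand$threshold[best] - 0.5))]
}
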