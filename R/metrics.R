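# Slide-level evaluation: AUC (rank statistic, ties counted half),
# accuracy at a 0.5 probability threshold, and macro-averaged F1.

#' Slide-level classification metrics
#'
#' Computes the area under the ROC curve as the Wilcoxon rank statistic
#' (tied scores count one half), accuracy with the positive-class
#' probability thresholded at 0.5, and the unweighted (macro) mean of the
#' per-class F1 scores.
#'
#' @param labels integer vector of 0/1 slide labels.
#' @param scores numeric vector of positive-class probabilities (or any
#'   monotone score for AUC; accuracy/F1 threshold at 0.5).
#' @return an object of class `metric_report`: a list with `auc` (NA when
#'   only one class is present), `acc`, `macro_f1`, `n_slides`, and the
#'   binary confusion counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc # 0.75
#' @export
compute_metrics <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  auc <- if (npos == 0L || nneg == 0L) {
    NA_real_
  } else {
    r <- rank(scores) # midranks handle ties as half-concordant
    (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  pred <- as.integer(scores > 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  acc <- (tp + tn) / length(labels)
  f1_class <- function(tp, fp, fn) {
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  macro_f1 <- mean(c(f1_class(tp, fp, fn), f1_class(tn, fn, fp)))
  structure(
    list(auc = auc, acc = acc, macro_f1 = macro_f1,
         n_slides = length(labels), tp = tp, fp = fp, fn = fn, tn = tn),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: n=%d  AUC=%s  ACC=%.4f  macro-F1=%.4f\n",
              x$n_slides,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc),
              x$acc, x$macro_f1))
  invisible(x)
}
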