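#' Binary classification metrics
#'
#' Computes true-positive rate, precision, recall, F-measure, Matthews
#' correlation coefficient and (when scores are supplied) the area under
#' the ROC curve from a confusion vector. Undefined ratios
#' (zero denominators) are reported as 0 and flagged.
#'
#' @param confusion Named numeric vector with elements `TP`, `FP`, `FN`,
#'   `TN` (non-negative).
#' @param scores Optional numeric scores (higher = more positive) for AUC.
#' @param labels Optional logical labels aligned with `scores`.
#' @return An object of class `evaluation_report`: list with `tp_rate`,
#'   `precision`, `recall`, `f_measure`, `mcc`, `auc`, `confusion`,
#'   `n_runs`, `degenerate` (TRUE when some ratio had a zero denominator).
#' @export
compute_metrics <- function(confusion, scores = NULL, labels = NULL) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(confusion)),
            all(confusion >= 0))
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  fn <- confusion[["FN"]]; tn <- confusion[["TN"]]
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f_measure <- if (precision + recall == 0) { degenerate <- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { degenerate <- TRUE; 0 } else
    (tp * tn - fp * fn) / mcc_den
  auc <- if (!is.null(scores)) {
    stopifnot(length(scores) == length(labels))
    auc_rank(scores, labels)
  } else NA_real_
  structure(
    list(tp_rate = recall, precision = precision, recall = recall,
         f_measure = f_measure, mcc = mcc, auc = auc,
         confusion = confusion, n_runs = 1L, degenerate = degenerate),
    class = "evaluation_report")
}

# AUC as the Mann-Whitney rank statistic (ties get average ranks), so it is
# invariant under strictly monotone transformations of the scores
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> (averaged over %d run(s))\n",
                     "  TP rate   %.3f\n  Precision %.3f\n  Recall    %.3f\n",
                     "  F-Measure %.3f\n  MCC       %.3f\n  AUC       %s\n"),
              x$n_runs, x$tp_rate, x$precision, x$recall, x$f_measure, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}
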