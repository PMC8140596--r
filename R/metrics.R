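# Classification performance metrics computed from a 2x2 confusion table,
# and the rank-based AUC.

#' Confusion-table performance metrics
#'
#' Computes the full metric set from the four confusion counts:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), F-measure = harmonic
#' mean of precision and recall, and Cohen's kappa from the 2x2 table.
#' A metric with a zero denominator is reported as 0 and its name recorded
#' in the `undefined` field, so every group receives a complete row.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts, total > 0.
#' @return A `metric_set`: list with the four counts, the seven metrics, and
#'   `undefined` (character vector of flagged metric names).
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("data error: confusion counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("data error: empty confusion table")
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    num / den
  }
  accuracy <- (tp + tn) / n
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  precision <- ratio(tp, tp + fp, "precision")
  f_measure <- if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f_measure")
    0
  } else 2 * precision * sensitivity / (precision + sensitivity)
  po <- accuracy
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (1 - pe == 0) {
    undefined <- c(undefined, "cohens_kappa")
    0
  } else (po - pe) / (1 - pe)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, recall = sensitivity,
                 precision = precision, f_measure = f_measure,
                 cohens_kappa = kappa, undefined = undefined),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "metric_set (tp=%d fp=%d tn=%d fn=%d): acc=%.3f sens=%.3f spec=%.3f prec=%.3f F=%.3f kappa=%.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$accuracy, x$sensitivity, x$specificity,
    x$precision, x$f_measure, x$cohens_kappa))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive sample receives a higher score than a randomly chosen negative
#' sample, with ties counted one half. Invariant to any monotone transform
#' of the scores.
#'
#' @param scores Numeric positive-class scores, one per sample.
#' @param labels Class labels, one per sample.
#' @param positive The label counted as positive.
#' @return AUC in \[0, 1\], or `NA` if either class is absent.
#' @export
auc_score <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  is_pos <- as.character(labels) == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: one class absent")
    return(NA_real_)
  }
  r <- rank(scores)  # midranks handle ties as 1/2 wins
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
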