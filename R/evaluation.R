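#' Slide-level evaluation against ground truth
#'
#' Builds the confusion matrix (positive class = HER2-positive) and the
#' four single-class metrics: accuracy, precision, recall, F1. A metric
#' whose denominator is zero is reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param predictions named 0/1 vector (or list) keyed by slide_id.
#' @param truth named 0/1 vector with exactly the same key set.
#' @return an object of class `evaluation_report`: list with `TP`, `FP`,
#'   `TN`, `FN`, `n`, `accuracy`, `precision`, `recall`, `f1`.
#' @examples
#' evaluate_predictions(c(a = 1, b = 0), c(a = 1, b = 1))
#' @export
evaluate_predictions <- function(predictions, truth) {
  predictions <- unlist(predictions); truth <- unlist(truth)
  extra <- setdiff(names(predictions), names(truth))
  missing <- setdiff(names(truth), names(predictions))
  if (length(extra) || length(missing)) {
    stop("key mismatch between predictions and truth",
         if (length(missing)) paste0("; missing predictions for: ",
                                     paste(sQuote(missing), collapse = ", ")),
         if (length(extra)) paste0("; predictions without truth: ",
                                   paste(sQuote(extra), collapse = ", ")))
  }
  pred <- as.integer(predictions[names(truth)])
  tr <- as.integer(truth)
  stopifnot(all(pred %in% c(0L, 1L)), all(tr %in% c(0L, 1L)))
  TP <- sum(pred == 1 & tr == 1); FP <- sum(pred == 1 & tr == 0)
  TN <- sum(pred == 0 & tr == 0); FN <- sum(pred == 0 & tr == 1)
  evaluation_report(TP, FP, TN, FN)
}

#' Evaluation report from confusion-matrix counts
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return an `evaluation_report`.
#' @export
evaluation_report <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  TP <- as.integer(TP); FP <- as.integer(FP)
  TN <- as.integer(TN); FN <- as.integer(FN)
  n <- TP + FP + TN + FN
  precision <- if (TP + FP > 0) TP / (TP + FP) else {
    warning("precision undefined (no positive predictions)"); NA_real_
  }
  recall <- if (TP + FN > 0) TP / (TP + FN) else {
    warning("recall undefined (no positive slides)"); NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN, n = n,
                 accuracy = if (n > 0) (TP + TN) / n else NA_real_,
                 precision = precision, recall = recall, f1 = f1),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report> n =", x$n, "\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  fmt <- function(v) if (is.na(v)) "NA" else format(round(v, digits), nsmall = digits)
  cat(sprintf("  accuracy=%s precision=%s recall=%s F1=%s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall), fmt(x$f1)))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; `NA` with a warning when both are zero.
#'
#' @param precision,recall fractions in [0, 1].
#' @return fraction in [0, 1], or `NA`.
#' @examples
#' f1_from_pr(0.570, 0.883)   # ~0.693
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) {
    warning("F1 undefined when precision and recall are both zero")
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Integer confusion matrices consistent with rounded metrics
#'
#' Enumerates all integer confusion matrices on a test set of `n_pos`
#' positive and `n_neg` negative slides whose precision and recall round
#' (to `digits` decimals) to the given values — useful for recovering the
#' exact counts behind published summary metrics.
#'
#' @param n_pos,n_neg class sizes.
#' @param precision,recall target rounded values.
#' @param digits rounding precision of the published values (default 3).
#' @return data frame of consistent matrices with columns `TP`, `FP`,
#'   `TN`, `FN`, `accuracy`, `precision`, `recall`, `f1` (possibly
#'   zero-row).
#' @examples
#' consistent_confusion_matrices(60, 90, 0.570, 0.883)
#' @export
consistent_confusion_matrices <- function(n_pos, n_neg, precision, recall,
                                          digits = 3) {
  out <- list()
  for (TP in 0:n_pos) {
    if (round(TP / n_pos, digits) != round(recall, digits)) next
    for (FP in 0:n_neg) {
      if (TP + FP == 0) next
      if (round(TP / (TP + FP), digits) != round(precision, digits)) next
      FN <- as.integer(n_pos - TP); TN <- as.integer(n_neg - FP)
      out[[length(out) + 1L]] <- data.frame(
        TP = as.integer(TP), FP = as.integer(FP), TN = TN, FN = FN,
        accuracy = (TP + TN) / (n_pos + n_neg),
        precision = TP / (TP + FP), recall = TP / n_pos,
        f1 = 2 * TP / (2 * TP + FP + FN))
    }
  }
  if (length(out) == 0L) {
    return(data.frame(TP = integer(0), FP = integer(0), TN = integer(0),
                      FN = integer(0), accuracy = numeric(0),
                      precision = numeric(0), recall = numeric(0),
                      f1 = numeric(0)))
  }
  do.call(rbind, out)
}
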