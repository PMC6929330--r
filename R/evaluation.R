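#' Confusion counts at a decision threshold
#'
#' A prediction is positive iff its probability is greater than or equal
#' to the threshold (ties count as positive; this is the documented rule).
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param threshold decision cutoff, default 0.5.
#' @return An object of class `confusion_counts`: list with integer
#'   fields `TP`, `FP`, `TN`, `FN` summing to the number of samples.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  if (length(probabilities) == 0L) stop("no predictions to evaluate")
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have the same length")
  pred <- probabilities >= threshold
  y <- labels == "positive"
  structure(list(TP = sum(pred & y), FP = sum(pred & !y),
                 TN = sum(!pred & !y), FN = sum(!pred & y)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' * sensitivity = TP / (TP + FN)
#' * specificity = TN / (TN + FP)
#' * accuracy = (TP + TN) / (TP + TN + FP + FN)
#' * MCC = (TP * TN - FP * FN) /
#'   sqrt((TP + FP)(TP + FN)(TN + FP)(TN + FN))
#'
#' Degenerate cases follow the usual conventions: a zero denominator in
#' sensitivity or specificity yields 0, and MCC is 0 whenever any factor
#' under the square root is 0.
#'
#' @param counts a [confusion_counts()] object or a list/vector with
#'   elements `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector with elements `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  if (total <= 0) stop("confusion counts are empty")
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  acc <- (tp + tn) / total
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(sensitivity = sens, specificity = spec, accuracy = acc, mcc = mcc)
}

#' ROC curve and AUC
#'
#' The ROC is swept over all distinct scores (prediction positive iff
#' score >= threshold), yielding points from (0, 0) to (1, 1); the AUC is
#' the trapezoidal area, which equals the Mann-Whitney U statistic
#' normalised by `n_pos * n_neg` with ties counted one half.
#'
#' @param probabilities scores (any monotone transform gives the same
#'   curve).
#' @param labels binary labels; both classes must be present.
#' @return List with `roc` (data.frame with columns `fpr`, `tpr`) and
#'   `auc` (scalar).
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as_binary_labels(labels)
  y <- labels == "positive"
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes to be present")
  ord <- order(probabilities, decreasing = TRUE)
  y_ord <- y[ord]
  p_ord <- probabilities[ord]
  # cumulative counts at each distinct score (threshold = that score)
  block_end <- which(!duplicated(p_ord, fromLast = TRUE))
  tp <- cumsum(y_ord)[block_end]
  fp <- cumsum(!y_ord)[block_end]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1L) + tail(roc$tpr, -1L)) / 2)
  list(roc = roc, auc = auc)
}

#' Full evaluation report for one model on one split
#'
#' @param probabilities predicted probabilities.
#' @param labels binary labels.
#' @param threshold decision cutoff for the thresholded metrics.
#' @return An object of class `eval_report`: sensitivity, specificity,
#'   accuracy, mcc, auc, the ROC points, the threshold, and per-class
#'   support.
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5) {
  labels <- as_binary_labels(labels)
  counts <- confusion_counts(probabilities, labels, threshold)
  m <- classification_metrics(counts)
  ra <- roc_auc(probabilities, labels)
  structure(list(sensitivity = unname(m["sensitivity"]),
                 specificity = unname(m["specificity"]),
                 accuracy = unname(m["accuracy"]),
                 mcc = unname(m["mcc"]),
                 auc = ra$auc, roc = ra$roc,
                 counts = counts, threshold = threshold,
                 support = c(positive = sum(labels == "positive"),
                             negative = sum(labels == "negative"))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> n=%d (%d pos / %d neg), ",
                     "threshold %.2f\n"),
              sum(x$support), x$support["positive"], x$support["negative"],
              x$threshold))
  cat(sprintf(paste0("  sensitivity %.3f  specificity %.3f  accuracy %.3f",
                     "  MCC %.3f  AUC %.3f\n"),
              x$sensitivity, x$specificity, x$accuracy, x$mcc, x$auc))
  invisible(x)
}
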