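#' Classification metrics from a binary confusion matrix
#'
#' Computes the validation metrics used throughout the package: accuracy,
#' precision, F-measure and G-mean, together with the recall (sensitivity)
#' and specificity they derive from. Precision, F-measure and G-mean are
#' reported because they stay informative under class imbalance; the G-mean
#' is the geometric mean of sensitivity and specificity,
#' \eqn{\sqrt{TPR \times TNR}}. Undefined ratios (zero denominators) are
#' reported as 0, the usual convention for degenerate classifiers.
#'
#' @param tp,fp,tn,fn non-negative confusion-matrix counts (true/false
#'   positives and negatives); their sum must be positive.
#' @return named numeric vector with elements `accuracy`, `precision`,
#'   `recall`, `specificity`, `f_score`, `g_mean`, all in \[0, 1\].
#' @examples
#' metrics_from_confusion(tp = 8, fp = 2, tn = 5, fn = 5)
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || anyNA(counts)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all-zero confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f_score <- safe_div(2 * precision * recall, precision + recall)
  c(
    accuracy = (tp + tn) / total,
    precision = precision,
    recall = recall,
    specificity = specificity,
    f_score = f_score,
    g_mean = sqrt(recall * specificity)
  )
}

confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0),
    fn = sum(pred == 0 & truth == 1))
}
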