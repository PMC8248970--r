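#' Binary classification performance metrics
#'
#' The three metrics used to compare predictive models built on harmonized
#' features:
#' * AUC — via the rank (Mann-Whitney) formulation with mid-ranks for
#'   ties, so it is invariant to strictly monotone transformations of the
#'   scores;
#' * balanced accuracy — the mean of sensitivity and specificity at the
#'   given score threshold, appropriate under class imbalance;
#' * Matthews correlation coefficient — the Pearson correlation between
#'   predicted and true labels computed from the 2x2 confusion matrix,
#'   defined as 0 when a marginal factor of its denominator is 0.
#'
#' @param y_true Binary ground-truth labels (0/1 numeric or logical); both
#'   classes must be present.
#' @param scores Numeric prediction scores, higher meaning more likely
#'   positive.
#' @param threshold Score threshold for the thresholded metrics
#'   (default 0.5).
#' @return A one-row tibble with columns `auc`, `bacc`, `mcc`.
#' @examples
#' classification_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
classification_metrics <- function(y_true, scores, threshold = 0.5) {
  if (is.logical(y_true)) y_true <- as.integer(y_true)
  if (!all(y_true %in% c(0, 1))) {
    abort("`y_true` must be binary 0/1.", class = "tlcombat_error_input")
  }
  if (length(y_true) != length(scores)) {
    abort("`y_true` and `scores` must have the same length.",
          class = "tlcombat_error_input")
  }
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("Both classes must be present in `y_true`.",
          class = "tlcombat_error_input")
  }

  r <- rank(scores) # mid-ranks on ties
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  fp <- sum(pred == 1 & y_true == 0)
  bacc <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)

  tibble(auc = auc, bacc = bacc, mcc = mcc)
}
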