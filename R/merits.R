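#' Number of misclassifications
#'
#' @param labels True 0/1 class labels.
#' @param predicted Predicted 0/1 class labels of the same length.
#' @return Nonnegative integer count of disagreements.
#' @export
nmc <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop_input("labels and predictions differ in length")
  }
  sum(labels != predicted)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen case scores strictly above a
#' randomly chosen control, with ties counted one half; equivalently the
#' normalized Mann-Whitney U statistic, computed via midranks.
#'
#' @param labels True 0/1 class labels (both classes present).
#' @param scores Continuous classifier scores, larger meaning more
#'   case-like.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(scores)) {
    stop_input("labels and scores differ in length")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discriminant Q2
#'
#' Prediction Q2 in which a residual is not penalized once the prediction
#' lies beyond its class label: a case (label 1) predicted at or above 1,
#' or a control (label 0) predicted at or below 0, contributes zero.
#' `DQ2 = 1 - PRESSD / TSS` with `TSS = sum((label - mean(label))^2)`.
#' DQ2 is never below the raw-residual Q2, with equality exactly when no
#' prediction overshoots its label.
#'
#' @param labels True 0/1 class labels (both classes present).
#' @param predictions Continuous predicted responses.
#' @return DQ2, a real number `<= 1` (negative for models worse than the
#'   class mean).
#' @export
dq2 <- function(labels, predictions) {
  labels <- check_binary_labels(labels)
  if (length(labels) != length(predictions)) {
    stop_input("labels and predictions differ in length")
  }
  resid <- labels - predictions
  resid[labels == 1 & predictions >= 1] <- 0
  resid[labels == 0 & predictions <= 0] <- 0
  tss <- sum((labels - mean(labels))^2)
  1 - sum(resid^2) / tss
}
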