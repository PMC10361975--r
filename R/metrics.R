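#' Classification metrics for one scored test set
#'
#' AUC is the tie-averaged rank statistic (the Mann-Whitney form of the
#' ROC area): with ranks computed over all scores, `AUC = (sum of positive
#' ranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`; constant scores give
#' exactly 0.5. Recall, precision and F1 come from the confusion table at
#' the score threshold (a sample is called positive when its score is at
#' least the threshold); precision is defined as 0 when nothing is called
#' positive, and F1 as 0 when precision and recall are both 0.
#'
#' @param scores Numeric predicted scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present (the ROC area is
#'   undefined otherwise).
#' @param threshold Decision threshold on the score (default 0.5, for
#'   probability-scaled scores).
#' @return Named numeric vector `c(auc, recall, precision, f1)`, all in
#'   [0, 1].
#' @export
#' @examples
#' evaluate(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
evaluate <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("labels contain a single class; AUC is undefined", call. = FALSE)
  }
  r <- rank(scores)                         # ties get averaged ranks
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  recall <- tp / (tp + fn)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(auc = auc, recall = recall, precision = precision, f1 = f1)
}
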