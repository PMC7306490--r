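# ROC curve and AUC by the rank (Mann-Whitney) identity.

#' ROC curve and AUC for a scalar score
#'
#' The AUC is computed through the Mann-Whitney identity: the fraction
#' of (positive, negative) pairs in which the positive scores higher,
#' with half credit for ties -- equivalently
#' `(sum of positive midranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`.
#' The curve enumerates every distinct score as a threshold
#' ("score >= threshold" calls positive) and reports (FPR, TPR).
#'
#' @param scores numeric, higher = more positive-like.
#' @param labels vector of class labels.
#' @param positive the label counted as positive.
#' @return list with `auc` and `curve` (data.frame: threshold, fpr,
#'   tpr, including the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels, positive = "stroke") {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_param("both classes must be present (got %d positive, %d negative)",
               n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))))
  list(auc = auc, curve = curve)
}
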