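# Evaluation metric suite: ROC-AUC (Mann-Whitney, half credit for ties),
# PRC-AUC (average precision, step interpolation), recall and zero-one loss
# at a fixed decision threshold.

.mf_check_scores <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1",
                                        call. = FALSE)
  labels
}

#' ROC-AUC
#'
#' Area under the receiver operating characteristic curve, computed as the
#' Mann-Whitney pairwise statistic `P(score+ > score-) + 0.5 P(tie)` via
#' average ranks, so tied scores receive half credit.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- .mf_check_scores(scores, labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("ROC-AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' PRC-AUC (average precision)
#'
#' Area under the precision-recall curve in the average-precision form:
#' the sum over descending score thresholds of the recall increment times
#' the precision at that threshold (step interpolation, no trapezoids,
#' avoiding the optimistic bias of linear interpolation). Tied scores are
#' collapsed into a single threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels with at least one positive.
#' @return average precision in `[0, 1]`.
#' @export
prc_auc <- function(scores, labels) {
  labels <- .mf_check_scores(scores, labels)
  npos <- sum(labels == 1L)
  if (npos == 0L)
    stop("PRC-AUC undefined: no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  ends <- which(c(diff(s) != 0, TRUE))  # last index of each tied block
  tp <- cumsum(y)[ends]
  prec <- tp / ends
  rec <- tp / npos
  sum((rec - c(0, rec[-length(rec)])) * prec)
}

#' Recall at a decision threshold
#'
#' `TP / (TP + FN)` with predictions thresholded at `threshold`.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels with at least one positive.
#' @param threshold decision threshold (default 0.5).
#' @return recall in `[0, 1]`.
#' @export
recall_at <- function(scores, labels, threshold = 0.5) {
  labels <- .mf_check_scores(scores, labels)
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("recall undefined: no positive labels", call. = FALSE)
  sum(scores >= threshold & labels == 1L) / npos
}

#' Zero-one loss
#'
#' Fraction of records whose thresholded prediction differs from the label
#' (equivalently `1 - accuracy` at the same threshold).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return misclassified fraction in `[0, 1]`.
#' @export
zero_one_loss <- function(scores, labels, threshold = 0.5) {
  labels <- .mf_check_scores(scores, labels)
  if (!length(labels)) stop("empty input", call. = FALSE)
  mean(as.integer(scores >= threshold) != labels)
}

.mf_bce <- function(scores, labels, eps = 1e-7) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Full metric suite for one score vector
#'
#' @param scores numeric prediction scores in `[0, 1]`.
#' @param labels binary labels.
#' @param threshold decision threshold for recall and zero-one loss.
#' @return named list with `loss` (binary cross-entropy), `roc_auc`,
#'   `prc_auc`, `recall` and `zero_one_loss`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- .mf_check_scores(scores, labels)
  list(loss = .mf_bce(scores, labels),
       roc_auc = roc_auc(scores, labels),
       prc_auc = prc_auc(scores, labels),
       recall = recall_at(scores, labels, threshold),
       zero_one_loss = zero_one_loss(scores, labels, threshold))
}
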