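#' Confusion-matrix and ranking metrics for binary scores
#'
#' Thresholds the continuous positive-class scores at `threshold` for the
#' confusion-matrix metrics and uses tie-aware ranking for AUC (equivalent
#' to trapezoidal integration of the ROC curve) and step-wise
#' precision-recall integration for AUPR. Undefined ratios (empty
#' denominator) are reported as `NaN` with a warning, never silently as 0.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @param threshold Decision threshold on the score (default 0.5).
#' @return Named list: `Acc`, `Prec`, `Sen`, `Spec`, `MCC`, `AUC`, `AUPR`,
#'   and the counts `TP`, `TN`, `FP`, `FN`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(scores) == 0) stop("empty test set", call. = FALSE)
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined: empty denominator",
                            call. = FALSE); return(NaN) }
    num / den
  }
  acc  <- (TP + TN) / length(labels)
  prec <- safe_div(TP, TP + FP, "precision")
  sen  <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined: empty denominator", call. = FALSE); NaN
  } else (TP * TN - FP * FN) / mcc_den
  list(Acc = acc, Prec = prec, Sen = sen, Spec = spec, MCC = mcc,
       AUC = auc_score(scores, labels), AUPR = aupr_score(scores, labels),
       TP = TP, TN = TN, FP = FP, FN = FN)
}

#' Area under the ROC curve (tie-aware rank statistic)
#'
#' Computed as the normalized Mann-Whitney statistic with average ranks,
#' which equals trapezoidal integration of the ROC curve over score
#' thresholds; identical scores for all samples give 0.5.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in `[0, 1]`, or `NaN` with a warning if one class is absent.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: one class absent", call. = FALSE)
    return(NaN)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step-wise integration)
#'
#' Samples are processed in descending score order, tie groups as one block;
#' the area accumulates `precision * delta-recall` at each block boundary.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (positives required).
#' @return AUPR in `[0, 1]`, or `NaN` with a warning if no positives.
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) { warning("AUPR undefined: no positives", call. = FALSE)
    return(NaN) }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  last <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cum_tp[last]; n <- cum_n[last]
  prec <- tp / n
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' ROC curve points over score thresholds
#' @param scores,labels Scores and 0/1 labels.
#' @return data.frame of `fpr`, `tpr` (tie groups collapsed), starting at
#'   (0,0) and ending at (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(y)[last]; n <- seq_along(y)[last]
  P <- sum(labels == 1); N <- sum(labels == 0)
  data.frame(fpr = c(0, (n - tp) / N), tpr = c(0, tp / P))
}

#' Precision-recall curve points over score thresholds
#' @param scores,labels Scores and 0/1 labels.
#' @return data.frame of `recall`, `precision` (tie groups collapsed).
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(y)[last]; n <- seq_along(y)[last]
  P <- sum(labels == 1)
  data.frame(recall = tp / P, precision = tp / n)
}
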