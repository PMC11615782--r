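#' Binary classification metrics from confusion counts
#'
#' Sensitivity (= recall), specificity, accuracy, precision, F1 and the
#' Matthews correlation coefficient from TP/TN/FP/FN counts. Any metric whose
#' denominator is zero is reported as 0 and flagged in the `degenerate`
#' attribute (with a warning), so aggregation across folds never drops a
#' fold.
#'
#' @param TP,TN,FP,FN nonnegative integer counts, total > 0.
#' @return named numeric vector with elements `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `f1`, `mcc`; attribute `degenerate` names any
#'   zero-denominator metrics.
#' @export
binary_metrics <- function(TP, TN, FP, FN) {
  cnt <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(is.na(cnt)) || any(cnt < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (sum(cnt) == 0) stop("empty confusion matrix", call. = FALSE)
  degen <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      degen <<- c(degen, name)
      return(0)
    }
    num / den
  }
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  acc <- (TP + TN) / sum(cnt)
  prec <- safe_div(TP, TP + FP, "precision")
  f1 <- if (prec + sens == 0) {
    degen <- c(degen, "f1")
    0
  } else {
    2 * prec * sens / (prec + sens)
  }
  mcc_den <- sqrt(TP + FN) * sqrt(TP + FP) * sqrt(TN + FN) * sqrt(TN + FP)
  mcc <- if (mcc_den == 0) {
    degen <- c(degen, "mcc")
    0
  } else {
    (TP * TN - FP * FN) / mcc_den
  }
  if (length(degen)) {
    warning("zero denominator for: ", paste(unique(degen), collapse = ", "),
            "; reported as 0", call. = FALSE)
  }
  structure(c(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, f1 = f1, mcc = mcc),
            degenerate = unique(degen))
}

#' Confusion counts from scores at a threshold
#'
#' @param scores numeric prediction scores/probabilities.
#' @param labels 0/1 labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  labels <- as.integer(labels)
  list(TP = sum(pred == 1 & labels == 1), TN = sum(pred == 0 & labels == 0),
       FP = sum(pred == 1 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' Threshold-free curves: ROC-AUC, AUPR, average precision
#'
#' ROC-AUC by trapezoidal integration over all score thresholds; AUPR by
#' trapezoidal integration of the precision-recall curve (step-wise
#' integration available via `pr_integration = "step"`, which makes `aupr`
#' equal `aps`); APS as step-wise average precision. Tied scores cross their
#' threshold simultaneously.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @param pr_integration `"trapezoid"` (default) or `"step"` for AUPR.
#' @return list with `roc_auc`, `aupr`, `aps`, `roc_curve` (fpr, tpr),
#'   `pr_curve` (recall, precision).
#' @export
threshold_curves <- function(scores, labels, pr_integration = c("trapezoid", "step")) {
  pr_integration <- match.arg(pr_integration)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  roc_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # PR curve starts at (recall of first block, its precision)
  rec_full <- c(0, recall)
  prec_full <- c(precision[1], precision)
  aupr_trap <- sum(diff(rec_full) * (utils::head(prec_full, -1) +
                                       utils::tail(prec_full, -1)) / 2)
  aps <- sum(diff(rec_full) * precision)
  aupr <- if (pr_integration == "trapezoid") aupr_trap else aps
  list(roc_auc = roc_auc, aupr = aupr, aps = aps,
       roc_curve = data.frame(fpr = fpr, tpr = tpr),
       pr_curve = data.frame(recall = rec_full, precision = prec_full))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true observed values (non-constant, length >= 2).
#' @param y_pred predicted values.
#' @return numeric R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2L) stop("need >= 2 samples", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("`y_true` is constant; R^2 undefined", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}
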