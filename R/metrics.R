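# Classification metrics. AUC is the rank-based ROC area (ties count 1/2),
# AP the step-wise precision-recall area over unique descending thresholds;
# both are computed only when both classes are present, otherwise an explicit
# NA "undefined" marker is reported.

#' ROC area under the curve
#' @param prob predicted probabilities.
#' @param label 0/1 (or logical) outcomes.
#' @return AUC in \[0,1\]; NA if a class is absent.
#' @export
roc_auc <- function(prob, label) {
  y <- as.integer(label)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise precision-recall area)
#'
#' Sum over unique descending score thresholds of
#' `(recall_k - recall_{k-1}) * precision_k`; tied scores enter as one block,
#' so the result does not depend on input order.
#'
#' @inheritParams roc_auc
#' @return AP in \[0,1\]; NA if a class is absent.
#' @export
average_precision <- function(prob, label) {
  y <- as.integer(label)
  npos <- sum(y == 1L)
  if (npos == 0L || all(y == 1L)) return(NA_real_)
  th <- sort(unique(prob), decreasing = TRUE)
  tp <- cumsum(vapply(th, function(t) sum(y == 1L & prob == t), numeric(1)))
  np <- cumsum(vapply(th, function(t) sum(prob == t), numeric(1)))
  prec <- tp / np
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion matrix at a probability threshold
#'
#' A compound is predicted positive when its probability is `>= threshold`.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold.
#' @return named integer vector (TP, FP, FN, TN).
#' @export
confusion_counts <- function(prob, label, threshold = 0.5) {
  y <- as.integer(label)
  p <- as.integer(prob >= threshold)
  c(TP = sum(p == 1L & y == 1L), FP = sum(p == 1L & y == 0L),
    FN = sum(p == 0L & y == 1L), TN = sum(p == 0L & y == 0L))
}

#' Matthews correlation coefficient from confusion counts
#' @param cm named vector with TP, FP, FN, TN.
#' @return MCC in \[-1,1\]; 0 when any marginal is empty.
#' @export
mcc_from_confusion <- function(cm) {
  tp <- as.numeric(cm["TP"]); fp <- as.numeric(cm["FP"])
  fn <- as.numeric(cm["FN"]); tn <- as.numeric(cm["TN"])
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Balanced accuracy from confusion counts
#'
#' Mean of sensitivity and specificity. When one class is absent its term is
#' dropped from the average, so one-class strata still report the accuracy
#' of the class that is present.
#'
#' @param cm named vector with TP, FP, FN, TN.
#' @return balanced accuracy in \[0,1\]; NA only when the input is empty.
#' @export
balanced_accuracy_from_confusion <- function(cm) {
  tp <- as.numeric(cm["TP"]); fp <- as.numeric(cm["FP"])
  fn <- as.numeric(cm["FN"]); tn <- as.numeric(cm["TN"])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (all(is.na(c(sens, spec)))) return(NA_real_)
  mean(c(sens, spec), na.rm = TRUE)
}

#' Brier score
#' @inheritParams roc_auc
#' @return mean squared difference between probability and outcome.
#' @export
brier_score <- function(prob, label) mean((prob - as.integer(label))^2)

#' Evaluate probabilities against labels
#'
#' @inheritParams confusion_counts
#' @return list: `auc`, `ap` (NA when one class absent), `mcc`,
#'   `balanced_accuracy`, `confusion`, `threshold_used`, `n`.
#' @export
evaluate_predictions <- function(prob, label, threshold = 0.5) {
  cm <- confusion_counts(prob, label, threshold)
  list(auc = roc_auc(prob, label), ap = average_precision(prob, label),
       mcc = mcc_from_confusion(cm),
       balanced_accuracy = balanced_accuracy_from_confusion(cm),
       confusion = cm, threshold_used = threshold, n = length(prob))
}

#' Probability calibration curve and Brier score
#'
#' Ten equal-width bins over \[0,1\] (the last bin closed); empty bins are
#' omitted from the curve but counts always conserve `n`.
#'
#' @inheritParams roc_auc
#' @param n_bins number of equal-width bins.
#' @return list with `curve` (data.frame `bin`, `lo`, `hi`, `n`,
#'   `mean_predicted`, `observed_positive_fraction`, empty bins omitted) and
#'   `brier`.
#' @export
calibrate <- function(prob, label, n_bins = 10L) {
  stopifnot(length(prob) >= 1L, length(prob) == length(label))
  y <- as.integer(label)
  bin <- pmin(floor(prob * n_bins) + 1L, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    i <- which(bin == b)
    if (length(i) == 0L) return(NULL)
    data.frame(bin = b, lo = (b - 1) / n_bins, hi = b / n_bins,
               n = length(i), mean_predicted = mean(prob[i]),
               observed_positive_fraction = mean(y[i]))
  })
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  list(curve = curve, brier = brier_score(prob, y))
}

#' Select a decision threshold from out-of-fold predictions
#'
#' Candidates are 0, 1 and the midpoints between consecutive sorted unique
#' OOF probabilities. The candidate maximizing the criterion on the OOF set
#' is selected (ties -> smallest candidate) and then applied, frozen, to the
#' test predictions.
#'
#' @param oof_prob,oof_label out-of-fold probabilities and labels (both
#'   classes must be present).
#' @param criterion "mcc" (default) or "balanced_accuracy".
#' @param test_prob,test_label optional held-out predictions to score at the
#'   frozen threshold.
#' @return list: `threshold`, `criterion`, `oof_value`, and when test data
#'   supplied `test_metrics` (mcc, balanced_accuracy, precision, recall, f1,
#'   specificity at the frozen threshold).
#' @export
select_threshold <- function(oof_prob, oof_label,
                             criterion = c("mcc", "balanced_accuracy"),
                             test_prob = NULL, test_label = NULL) {
  criterion <- match.arg(criterion)
  y <- as.integer(oof_label)
  if (length(unique(y)) < 2L) stop("both classes required")
  u <- sort(unique(oof_prob))
  cand <- unique(c(0, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, 1))
  score <- vapply(cand, function(t) {
    cm <- confusion_counts(oof_prob, y, t)
    if (criterion == "mcc") mcc_from_confusion(cm)
    else balanced_accuracy_from_confusion(cm)
  }, numeric(1))
  best <- cand[which.max(score)] # which.max takes the first (smallest) tie
  out <- list(threshold = best, criterion = criterion,
              oof_value = max(score))
  if (!is.null(test_prob)) {
    cm <- confusion_counts(test_prob, as.integer(test_label), best)
    tp <- as.numeric(cm["TP"]); fp <- as.numeric(cm["FP"])
    fn <- as.numeric(cm["FN"]); tn <- as.numeric(cm["TN"])
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$test_metrics <- list(
      mcc = mcc_from_confusion(cm),
      balanced_accuracy = balanced_accuracy_from_confusion(cm),
      precision = prec, recall = rec,
      f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      confusion = cm
    )
  }
  out
}
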