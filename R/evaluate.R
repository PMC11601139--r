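#' Confusion matrix for the binary ADR/non-ADR task
#'
#' The positive class is ADR (label 1).
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return An object of class `adr_confusion`: list with integer counts
#'   `tp`, `fp`, `fn`, `tn` and `total`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    abort_adr(sprintf("length mismatch: %d true vs %d predicted",
                      length(y_true), length(y_pred)), "adr_validation_error")
  if (length(y_true) < 1)
    abort_adr("confusion requires at least one observation", "adr_validation_error")
  if (!is_binary01(y_true) || !is_binary01(y_pred))
    abort_adr("labels and predictions must be 0 or 1", "adr_validation_error")
  confusion_counts(tp = sum(y_true == 1 & y_pred == 1),
                   fp = sum(y_true == 0 & y_pred == 1),
                   fn = sum(y_true == 1 & y_pred == 0),
                   tn = sum(y_true == 0 & y_pred == 0))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative integer counts, for building a confusion
#'   matrix directly from published tables.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_adr("confusion counts must be non-negative integers", "adr_validation_error")
  total <- sum(counts)
  if (total < 1)
    abort_adr("confusion matrix must contain at least one observation",
              "adr_validation_error")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 total = as.integer(total)),
            class = "adr_confusion")
}

#' Derived metrics from a confusion matrix
#'
#' accuracy = (tp+tn)/total, precision = tp/(tp+fp), recall = tp/(tp+fn),
#' F1 = 2 tp / (2 tp + fp + fn), all for the positive (ADR) class. Ratios
#' with a zero denominator are reported as `NA` with a warning, never
#' silently coerced to 0.
#'
#' @param cm an `adr_confusion`.
#' @return list with `accuracy`, `precision`, `recall`, `f1` (fractions on
#'   0-1).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "adr_confusion"))
  ratio <- function(num, den, name) {
    if (den == 0) {
      warn_adr(sprintf("%s undefined (zero denominator)", name),
               "adr_undefined_metric")
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f1")
  list(accuracy = (cm$tp + cm$tn) / cm$total,
       precision = precision, recall = recall, f1 = f1)
}

#' @export
print.adr_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(actual = c("non-ADR", "ADR"),
                              predicted = c("non-ADR", "ADR")))
  print(m)
  invisible(x)
}

#' ROC curve over a threshold sweep
#'
#' Classifies the scores at every threshold via [classify()], records the
#' (false-positive rate, true-positive rate) point per threshold, and
#' integrates the area under the curve by the trapezoidal rule. The AUC uses
#' all distinct scores as cut points (never grid-coarsened); accuracy is
#' additionally reported on the printed-style grid 0.1, 0.2, ..., 1.0.
#'
#' @param y_true 0/1 vector containing both classes.
#' @param scores numeric scores in \[0, 1\].
#' @param grid thresholds at which to report accuracy; defaults to
#'   `seq(0.1, 1, 0.1)`.
#' @return An object of class `adr_roc`: list with `thresholds` (descending
#'   sweep including the all-negative endpoint), `points` (data.frame
#'   threshold/fpr/tpr), `auc`, and `accuracy_by_threshold` (data.frame
#'   threshold/accuracy over `grid`).
#' @export
roc <- function(y_true, scores, grid = seq(0.1, 1, by = 0.1)) {
  if (length(y_true) != length(scores))
    abort_adr("length mismatch between labels and scores", "adr_validation_error")
  if (!is_binary01(y_true))
    abort_adr("y_true must be 0/1", "adr_validation_error")
  stopifnot(all(scores >= 0 & scores <= 1))
  if (length(unique(y_true)) < 2)
    abort_adr("ROC/AUC undefined: y_true contains a single class",
              "adr_validation_error")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  # descending sweep: start above max(scores) (all-negative endpoint, the
  # (0,0) corner), end at 0 (all-positive, the (1,1) corner)
  thr <- c(1.000001, sort(unique(scores), decreasing = TRUE), 0)
  thr <- unique(thr)
  pts <- t(vapply(thr, function(t) {
    pred <- as.integer(scores >= t)
    c(fpr = sum(pred == 1 & y_true == 0) / n_neg,
      tpr = sum(pred == 1 & y_true == 1) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                     utils::tail(pts[, "tpr"], -1)) / 2)
  acc <- vapply(grid, function(t)
    mean(classify(scores, t) == y_true), 0)
  structure(list(thresholds = thr,
                 points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                                     tpr = pts[, "tpr"]),
                 auc = auc,
                 accuracy_by_threshold = data.frame(threshold = grid,
                                                    accuracy = acc)),
            class = "adr_roc")
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement between two binary label vectors:
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and chance
#' agreement p_e from the marginals. The degenerate case p_e = 1 with
#' perfect observed agreement returns 1.
#'
#' @param labels_a,labels_b equal-length 0/1 vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    abort_adr("annotator label vectors differ in length", "adr_validation_error")
  if (length(labels_a) < 1)
    abort_adr("kappa requires at least one item", "adr_validation_error")
  if (!is_binary01(labels_a) || !is_binary01(labels_b))
    abort_adr("annotator labels must be 0 or 1", "adr_validation_error")
  n <- length(labels_a)
  po <- mean(labels_a == labels_b)
  pa1 <- mean(labels_a == 1); pb1 <- mean(labels_b == 1)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pe >= 1) return(if (po == 1) 1 else (po - pe) / .Machine$double.eps)
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for two or more annotators
#'
#' Standard Fleiss formulation for binary ratings; for 2 raters on balanced
#' data it is close to Cohen's kappa.
#'
#' @param ratings n_items x n_raters matrix of 0/1 ratings.
#' @return Fleiss' kappa.
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2)
    abort_adr("Fleiss' kappa requires at least 2 raters", "adr_validation_error")
  if (!is_binary01(as.vector(ratings)))
    abort_adr("ratings must be 0 or 1", "adr_validation_error")
  n <- nrow(ratings); m <- ncol(ratings)
  n1 <- rowSums(ratings)          # raters saying 1 per item
  counts <- cbind(m - n1, n1)      # category counts per item
  P_i <- (rowSums(counts^2) - m) / (m * (m - 1))
  p_j <- colSums(counts) / (n * m)
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (P_e >= 1) return(if (P_bar == 1) 1 else -Inf)
  (P_bar - P_e) / (1 - P_e)
}

#' Full evaluation report for a scored test set
#'
#' Convenience wrapper producing everything reported for a classifier run:
#' confusion matrix at the decision threshold, derived metrics, ROC sweep
#' and AUC.
#'
#' @param y_true 0/1 labels.
#' @param scores model scores in \[0, 1\].
#' @param threshold decision threshold.
#' @return list with `confusion`, `metrics`, `roc` (an `adr_roc`), `auc`,
#'   and `threshold`.
#' @export
evaluate_scores <- function(y_true, scores, threshold = 0.5) {
  cm <- confusion(y_true, classify(scores, threshold))
  rc <- roc(y_true, scores)
  list(confusion = cm, metrics = metrics(cm), roc = rc, auc = rc$auc,
       threshold = threshold)
}
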