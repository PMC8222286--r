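# Evaluation statistics: confusion counts at a fixed threshold, precision
# (PPV), recall (TPR), Matthews correlation, accuracy and ROC AUC.

#' Tally confusion counts at a decision threshold
#'
#' A score is called positive when `score >= threshold` (a score exactly at
#' the threshold counts as positive; the tie rule is fixed for
#' reproducibility). The default threshold 0.5 is the classical cut-off used
#' throughout the evaluation.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Binary (0/1) vector of the same length.
#' @param threshold Decision threshold.
#' @return Object of class `confusion_counts`: list with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores (", length(scores), ") and labels (", length(labels),
         ") differ in length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  pred <- scores >= threshold
  structure(list(TP = sum(pred & labels == 1L),
                 FP = sum(pred & labels == 0L),
                 TN = sum(!pred & labels == 0L),
                 FN = sum(!pred & labels == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

# 0-with-flag convention for empty denominators: benchmark subsets can be
# one-sided and must not crash the report.
flag_degenerate <- function(value, degenerate) {
  if (degenerate) attr(value, "degenerate") <- TRUE
  value
}

#' Positive predictive value (precision), TP / (TP + FP)
#'
#' @param counts A `confusion_counts` object.
#' @return PPV in \[0, 1\]; 0 with attribute `degenerate = TRUE` when
#'   `TP + FP == 0`.
#' @export
ppv <- function(counts) {
  den <- counts$TP + counts$FP
  if (den == 0) return(flag_degenerate(0, TRUE))
  counts$TP / den
}

#' True positive rate (recall), TP / (TP + FN)
#'
#' @inheritParams ppv
#' @return TPR in \[0, 1\]; 0 with attribute `degenerate = TRUE` when
#'   `TP + FN == 0`.
#' @export
tpr <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) return(flag_degenerate(0, TRUE))
  counts$TP / den
}

#' Matthews correlation coefficient
#'
#' `((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, computed in
#' doubles to avoid integer overflow; 0 with a `degenerate` attribute when
#' any factor of the denominator is zero.
#'
#' @inheritParams ppv
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(flag_degenerate(0, TRUE))
  (tp * tn - fp * fn) / sqrt(den)
}

#' Binary accuracy, (TP + TN) / n
#'
#' @inheritParams ppv
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  if (n == 0) return(flag_degenerate(0, TRUE))
  (counts$TP + counts$TN) / n
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a uniformly drawn positive
#' outscores a uniformly drawn negative, with ties credited 0.5. Computed
#' from midranks, which equals the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric vector of scores.
#' @param labels Binary (0/1) vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes; got ", n1, " positives and ",
         n0, " negatives")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained model on labeled windows
#'
#' Scores the windows with [predict_scores()] and reports accuracy, PPV,
#' TPR, MCC and AUC at the given threshold, plus the underlying confusion
#' counts. All windows must be valid. Also usable for the immunogenicity
#' benchmark by passing curated binary immunogenicity labels.
#'
#' @param model A `cleavage_model`.
#' @param windows Character vector of 7-residue windows.
#' @param labels Binary (0/1) labels, same length.
#' @param threshold Decision threshold.
#' @return Object of class `metric_report`: list with `accuracy`, `ppv`,
#'   `tpr`, `mcc`, `auc`, `counts`, `threshold`, `n`.
#' @export
evaluate_model <- function(model, windows, labels, threshold = 0.5) {
  scored <- predict_scores(model, windows)
  if (any(scored$status != "ok")) {
    bad <- which(scored$status != "ok")[1L]
    stop("invalid window at row ", bad, ": ", scored$status[bad])
  }
  metric_report(scored$score, labels, threshold = threshold)
}

#' Compute the full metric report from raw scores
#'
#' @param scores Numeric probabilities.
#' @param labels Binary (0/1) labels.
#' @param threshold Decision threshold.
#' @return A `metric_report`; see [evaluate_model()].
#' @export
metric_report <- function(scores, labels, threshold = 0.5) {
  counts <- confusion_at_threshold(scores, labels, threshold = threshold)
  structure(list(accuracy = as.numeric(accuracy(counts)),
                 ppv = as.numeric(ppv(counts)),
                 tpr = as.numeric(tpr(counts)),
                 mcc = as.numeric(mcc(counts)),
                 auc = roc_auc(scores, labels),
                 counts = counts,
                 threshold = threshold,
                 n = length(labels)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "n=%d @ threshold %.2f: accuracy %.4f | PPV %.4f | TPR %.4f | MCC %.4f | AUC %.4f\n",
    x$n, x$threshold, x$accuracy, x$ppv, x$tpr, x$mcc, x$auc))
  print(x$counts)
  invisible(x)
}

#' Serialize a metric report to JSON
#'
#' @param report A `metric_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  payload <- list(accuracy = report$accuracy, ppv = report$ppv,
                  tpr = report$tpr, mcc = report$mcc, auc = report$auc,
                  counts = unclass(report$counts),
                  threshold = report$threshold, n = report$n)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
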