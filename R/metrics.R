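#' Confusion matrix for a binary classifier
#'
#' The positive class is "active". Counts must be non-negative; `TP + FN`
#' is the number of actives and `TN + FP` the number of inactives.
#'
#' @param tp,fn,tn,fp non-negative integer counts.
#' @return an object of class `confusion_matrix`.
#' @examples
#' cm <- confusion_matrix(tp = 91, fn = 2, tn = 49, fp = 3)
#' mcc(cm)
#' @export
confusion_matrix <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_input("confusion matrix counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix: TP=%d FN=%d TN=%d FP=%d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

as_cm <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop_input("expected a confusion_matrix")
  cm
}

## counts from predicted/true labels (1 = active)
cm_from_labels <- function(pred, truth) {
  confusion_matrix(tp = sum(pred == 1 & truth == 1),
                   fn = sum(pred == 0 & truth == 1),
                   tn = sum(pred == 0 & truth == 0),
                   fp = sum(pred == 1 & truth == 0))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any factor
#' of the denominator is zero the correlation is undefined and 0 is
#' returned (the no-information convention).
#'
#' @param cm a [confusion_matrix()].
#' @return a number in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  cm <- as_cm(cm)
  tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
  tn <- as.numeric(cm$tn); fp <- as.numeric(cm$fp)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Accuracy, sensitivity, specificity and F-value
#'
#' Plain rational forms: `ACC = (TP+TN)/n`, `Sn = TP/(TP+FN)`,
#' `Sp = TN/(TN+FP)`, `F = 2TP/(2TP+FP+FN)`. A zero denominator yields 0
#' with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return a number in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  cm <- as_cm(cm)
  safe_ratio(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn, "accuracy")
}

#' @rdname accuracy
#' @export
sensitivity <- function(cm) {
  cm <- as_cm(cm)
  safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
}

#' @rdname accuracy
#' @export
specificity <- function(cm) {
  cm <- as_cm(cm)
  safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
}

#' @rdname accuracy
#' @export
f_value <- function(cm) {
  cm <- as_cm(cm)
  safe_ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "f_value")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning 0", what))
    return(0)
  }
  as.numeric(num) / as.numeric(den)
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen active scores
#' higher than a randomly chosen inactive, ties counted one half. Equivalent
#' to trapezoidal integration of the ROC curve.
#'
#' @param scores numeric predicted confidences.
#' @param y binary truth (1 = active, 0 = inactive; logicals and two-level
#'   factors are accepted).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as_binary01(y)
  if (length(scores) != length(y)) stop_input("scores and y differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_input("roc_auc undefined: both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(y == "active")
  if (!all(y %in% c(0, 1))) stop_input("labels must be binary (0/1 or active/inactive)")
  as.integer(y)
}

#' Full metrics report
#'
#' Computes ACC, Sn, Sp, MCC, F-value and (when scores are supplied) ROC AUC
#' from predictions against the truth, or directly from a confusion matrix.
#'
#' @param truth binary truth labels, or a [confusion_matrix()] (then `pred`
#'   and `scores` are ignored).
#' @param pred binary predicted labels.
#' @param scores optional predicted confidences for AUC.
#' @return an object of class `metrics_report` (a list with `acc`, `sn`,
#'   `sp`, `mcc`, `f_value`, `auc`, `cm`).
#' @export
metrics_report <- function(truth, pred = NULL, scores = NULL) {
  if (inherits(truth, "confusion_matrix")) {
    cm <- truth
    auc <- NA_real_
  } else {
    truth <- as_binary01(truth)
    pred <- as_binary01(pred)
    cm <- cm_from_labels(pred, truth)
    auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, truth)
  }
  structure(list(acc = accuracy(cm), sn = sensitivity(cm), sp = specificity(cm),
                 mcc = mcc(cm), f_value = f_value(cm), auc = auc, cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("ACC %.*f | Sn %.*f | Sp %.*f | MCC %.*f | F %.*f | AUC %s\n",
              digits, x$acc, digits, x$sn, digits, x$sp, digits, x$mcc,
              digits, x$f_value,
              if (is.na(x$auc)) "NA" else formatC(x$auc, digits = digits, format = "f")))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(acc = x$acc, sn = x$sn, sp = x$sp, mcc = x$mcc,
             f_value = x$f_value, auc = x$auc)
}

#' Compare several models in one table
#'
#' Builds the usual side-by-side comparison: one row per report, columns
#' ACC/Sn/Sp/MCC/AUC/F-value, sorted by MCC (descending). Differences
#' against a reference model are reported in percentage points
#' (`(value - reference) * 100`).
#'
#' @param reports a named list of [metrics_report()] objects.
#' @param reference name of the reference model for the difference columns;
#'   defaults to the first report.
#' @return a `data.frame` sorted by MCC, with `*_diff_pp` columns.
#' @export
compare_models <- function(reports, reference = names(reports)[1]) {
  if (length(reports) < 2) stop_input("compare_models needs at least two reports")
  if (is.null(names(reports)) || any(names(reports) == "")) {
    stop_input("reports must be a named list")
  }
  if (!reference %in% names(reports)) stop_input("unknown reference model '%s'", reference)
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  tab <- cbind(model = names(reports), tab)
  ref <- tab[tab$model == reference, ]
  for (m in c("acc", "sn", "sp", "mcc", "f_value", "auc")) {
    tab[[paste0(m, "_diff_pp")]] <- (tab[[m]] - ref[[m]]) * 100
  }
  tab <- tab[order(-tab$mcc), ]
  rownames(tab) <- NULL
  tab
}
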