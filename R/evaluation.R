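#' Confusion matrix for a labeled evaluation
#'
#' Tallies true/false positives and negatives with diabetes (`DM`) as the
#' positive class: TP = DM predicted DM, FP = non-DM predicted DM,
#' TN = non-DM predicted non-DM, FN = DM predicted non-DM.
#'
#' @param predictions Predicted labels (factor or character).
#' @param labels True labels, same length.
#' @param positive The positive class (default `"DM"`).
#' @return A `confusion_matrix` object with fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(predictions, labels, positive = "DM") {
  if (length(predictions) != length(labels)) {
    tn_stop("contract_error", "predictions (%d) and labels (%d) differ in length",
            length(predictions), length(labels))
  }
  p <- as.character(predictions) == positive
  l <- as.character(labels) == positive
  structure(list(TP = sum(p & l), FP = sum(p & !l),
                 TN = sum(!p & !l), FN = sum(!p & l),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (positive class: %s)\n", x$positive))
  cat(sprintf("  TP %d  FP %d\n  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' The six standard diagnostics: accuracy `(TP+TN)/total`, precision
#' `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, F1 `2*precision*recall/(precision+recall)` and error rate
#' `(FP+FN)/total` (the exact complement of accuracy). A metric whose
#' denominator is zero is reported as `NA` and listed in the `undefined`
#' attribute — never silently as 0.
#'
#' @param cm A [confusion_matrix()] (or a list with TP/FP/TN/FN counts).
#' @return A `metric_report`: named list of the six metrics, with an
#'   `undefined` character vector naming any undefined entries.
#' @export
classification_metrics <- function(cm) {
  counts <- c(cm$TP, cm$FP, cm$TN, cm$FN)
  if (any(counts < 0) || any(counts != floor(counts))) {
    tn_stop("argument_error", "confusion counts must be nonnegative integers")
  }
  total <- sum(counts)
  if (total < 1) tn_stop("argument_error", "confusion matrix is empty")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(cm$TP, cm$TP + cm$FP)
  sensitivity <- safe_div(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            (precision + sensitivity) == 0) NA_real_ else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  rep_ <- list(
    accuracy = (cm$TP + cm$TN) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_div(cm$TN, cm$TN + cm$FP),
    f1 = f1,
    error_rate = (cm$FP + cm$FN) / total
  )
  attr(rep_, "undefined") <- names(rep_)[vapply(rep_, is.na, TRUE)]
  class(rep_) <- "metric_report"
  rep_
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("Classification metrics\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else formatC(x[[nm]], digits = digits, format = "f")))
  }
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct scores in descending
#' order (ties grouped), with TPR = sensitivity and FPR = 1 - specificity;
#' the curve runs monotonically from (0, 0) to (1, 1) and the AUC is the
#' trapezoid-rule area. With identically-scored classes the curve is the
#' diagonal and AUC 0.5.
#'
#' @param scores Numeric scores for the positive class.
#' @param labels True labels.
#' @param positive The positive class (default `"DM"`).
#' @return A list with `points` (data.frame of `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = "DM") {
  if (length(scores) != length(labels)) {
    tn_stop("contract_error", "scores and labels differ in length")
  }
  l <- as.character(labels) == positive
  n_pos <- sum(l); n_neg <- sum(!l)
  if (n_pos == 0 || n_neg == 0) {
    tn_stop("argument_error", "ROC needs at least one positive and one negative label")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(l & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!l & scores >= t) / n_neg, 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Write a metric report as JSON and as a delimited table
#'
#' Emits one row per model with the six metric columns of the study's
#' comparison tables, as both a JSON document and a TSV table.
#'
#' @param reports Named list of `metric_report`s (names = model labels).
#' @param path_json,path_table Output paths (either may be NULL to skip).
#' @return The combined data.frame, invisibly.
#' @export
write_metric_report <- function(reports, path_json = NULL, path_table = NULL) {
  if (inherits(reports, "metric_report")) reports <- list(model = reports)
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, accuracy = r$accuracy, precision = r$precision,
               sensitivity = r$sensitivity, specificity = r$specificity,
               f1 = r$f1, error_rate = r$error_rate)
  }))
  if (!is.null(path_json)) {
    jsonlite::write_json(df, path_json, digits = NA, pretty = TRUE)
  }
  if (!is.null(path_table)) {
    utils::write.table(df, path_table, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
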