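# Confusion-matrix metrics and the rank-based (Mann-Whitney) AUC with the
# half-weight tie correction; macro averaging for multiclass reports.

#' Binary confusion counts
#'
#' Standard 2x2 tally of predictions against truth with respect to a
#' designated positive class.
#'
#' @param predicted vector of predicted labels.
#' @param truth vector of true labels, same length.
#' @param positive_class the label counted as positive.
#' @return a `confusion_counts` list with integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth))
    stopf("predicted (%d) and truth (%d) differ in length", length(predicted), length(truth))
  if (!length(truth)) stopf("empty input")
  pp <- predicted == positive_class
  tp <- truth == positive_class
  structure(list(TP = sum(pp & tp), FP = sum(pp & !tp),
                 TN = sum(!pp & !tp), FN = sum(!pp & tp)),
            class = "confusion_counts")
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Zero denominators
#' yield 0 by convention (noted via a message), so degenerate small runs
#' report rather than error.
#'
#' @param counts a [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @param quiet suppress the degenerate-denominator message.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(counts, quiet = FALSE) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  n <- tp + fp + tn + fn
  if (n <= 0) stopf("no evaluated items")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      if (!quiet) message(sprintf("%s denominator is 0; reporting 0 by convention", what))
      return(0)
    }
    num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall <- ratio0(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / n, precision = precision, recall = recall, f1 = f1)
}

#' Rank-based binary AUC with tie correction
#'
#' The Mann-Whitney pair statistic:
#' `AUC = 1 - (1/(m+ m-)) * [ #\{(x+, x-): f(x+) < f(x-)\} +
#'  (1/2) * #\{(x+, x-): f(x+) = f(x-)\} ]`,
#' computed via midranks (identical to the explicit pair enumeration).
#' Always in `[0, 1]`; 0.5 for all-tied scores; invariant under strictly
#' increasing score transforms.
#'
#' @param scores numeric prediction scores, higher = more positive.
#' @param truth logical vector (or any vector compared against
#'   `positive_class`) of true labels.
#' @param positive_class the label counted as positive (defaults to `TRUE`
#'   for logical truth; otherwise required).
#' @return the AUC.
#' @export
auc_binary <- function(scores, truth, positive_class = NULL) {
  stopifnot(length(scores) == length(truth))
  pos <- if (is.null(positive_class)) {
    if (!is.logical(truth)) stopf("positive_class is required for non-logical truth")
    truth
  } else truth == positive_class
  m_pos <- sum(pos); m_neg <- sum(!pos)
  if (m_pos == 0 || m_neg == 0)
    stopf("AUC needs at least one positive and one negative sample")
  r <- rank(scores)  # midranks handle the half-weight tie term
  (sum(r[pos]) - m_pos * (m_pos + 1) / 2) / (m_pos * m_neg)
}

#' Macro one-vs-rest multiclass AUC
#'
#' One binary AUC per class (that class's score column against
#' class-vs-rest truth), averaged with equal weight over the classes
#' present in `truth`; classes absent from `truth` are excluded with a
#' warning.
#'
#' @param score_matrix numeric matrix, one column per class, columns named
#'   by class label.
#' @param truth vector of true class labels.
#' @return the macro-averaged AUC.
#' @export
auc_macro_ovr <- function(score_matrix, truth) {
  stopifnot(is.matrix(score_matrix), !is.null(colnames(score_matrix)),
            nrow(score_matrix) == length(truth))
  classes <- colnames(score_matrix)
  present <- classes[classes %in% unique(truth)]
  absent <- setdiff(classes, present)
  if (length(absent))
    warnf("class(es) absent from truth excluded from macro AUC: %s",
          paste(absent, collapse = ", "))
  if (length(present) < 2 && length(unique(truth)) < 2)
    stopf("macro AUC needs at least two classes present in truth")
  mean(vapply(present, function(cl) auc_binary(score_matrix[, cl], truth == cl), numeric(1)))
}

#' Full evaluation report
#'
#' Per-class confusion counts plus accuracy/precision/recall/F1 and AUC.
#' Binary reports use the designated positive class; multiclass reports
#' macro-average the per-class metrics (one-vs-rest) and use the macro
#' one-vs-rest AUC. Overall accuracy is the plain fraction of correct
#' predictions in both cases.
#'
#' @param scores numeric matrix `N x K` of class scores, columns named by
#'   class label.
#' @param truth vector of true class labels.
#' @param positive_class positive class for binary reports (default:
#'   `"malignant"` when present, else the last column).
#' @param quiet passed to [classification_metrics()].
#' @return a `metrics_report` list: `averaging`, `per_class` (data frame
#'   of counts and metrics), and the headline `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`.
#' @export
metrics_report <- function(scores, truth, positive_class = NULL, quiet = TRUE) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            nrow(scores) == length(truth))
  classes <- colnames(scores)
  predicted <- classes[max.col(scores, ties.method = "first")]
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cc <- confusion_counts(predicted, truth, cl)
    m <- classification_metrics(cc, quiet = quiet)
    data.frame(class = cl, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               precision = m["precision"], recall = m["recall"], f1 = m["f1"],
               row.names = NULL)
  }))
  binary <- length(classes) == 2
  if (binary) {
    if (is.null(positive_class))
      positive_class <- if ("malignant" %in% classes) "malignant" else classes[2]
    cc <- confusion_counts(predicted, truth, positive_class)
    m <- classification_metrics(cc, quiet = quiet)
    auc <- auc_binary(scores[, positive_class], truth, positive_class)
    rep <- list(averaging = "binary", positive_class = positive_class,
                accuracy = unname(m["accuracy"]), precision = unname(m["precision"]),
                recall = unname(m["recall"]), f1 = unname(m["f1"]), auc = auc)
  } else {
    rep <- list(averaging = "macro",
                accuracy = mean(predicted == truth),
                precision = mean(per_class$precision),
                recall = mean(per_class$recall),
                f1 = mean(per_class$f1),
                auc = auc_macro_ovr(scores, truth))
  }
  rep$per_class <- per_class
  rep$n <- length(truth)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, n=%d\n", x$averaging, x$n))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  auc %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Write a metrics report as JSON
#' @param report a `metrics_report`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
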