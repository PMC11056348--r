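# Multi-class evaluation: confusion matrix, accuracy, one-vs-rest
# precision/recall/F1, macro and support-weighted aggregates.

#' Confusion matrix
#'
#' Counts with rows indexing the true class and columns the predicted
#' class, in the fixed order given by `classes`.
#'
#' @param truth,predicted Character (or factor) label vectors of equal
#'   length; every label must be one of `classes`.
#' @param classes Ordered class labels.
#' @return Integer matrix of class `sac_confusion` with `dimnames`
#'   `list(truth = classes, predicted = classes)`.
#' @export
confusion_matrix <- function(truth, predicted, classes) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  class(cm) <- c("sac_confusion", class(cm))
  cm
}

#' Overall accuracy from a confusion matrix
#'
#' `100 * trace / total`: the multi-class proportion of correct
#' predictions, in percent.
#'
#' @param cm A square count matrix (rows = truth, columns = predicted).
#' @return Percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has no observations")
  100 * sum(diag(as.matrix(cm))) / total
}

#' Per-class precision and recall
#'
#' One-vs-rest precision `100 * TP / (TP + FP)` (column-based) and recall
#' `100 * TP / (TP + FN)` (row-based) for each class. A zero denominator
#' yields 0 for that metric and raises the corresponding `degenerate` flag.
#'
#' @param cm A confusion matrix (rows = truth, columns = predicted).
#' @return A data.frame with columns `class`, `precision`, `recall`,
#'   `support`, `degenerate_precision`, `degenerate_recall`.
#' @export
precision_recall <- function(cm) {
  m <- as.matrix(cm)
  tp <- diag(m)
  col_tot <- colSums(m)
  row_tot <- rowSums(m)
  pr <- ifelse(col_tot > 0, 100 * tp / col_tot, 0)
  re <- ifelse(row_tot > 0, 100 * tp / row_tot, 0)
  data.frame(class = rownames(m),
             precision = unname(pr),
             recall = unname(re),
             support = unname(as.integer(row_tot)),
             degenerate_precision = unname(col_tot == 0),
             degenerate_recall = unname(row_tot == 0),
             row.names = NULL)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * pr * re / (pr + re)` (elementwise); defined as 0
#' where both inputs are 0.
#'
#' @param pr,re Precision and recall, in percent (vectors recycle).
#' @return F1 in percent.
#' @export
f1_score <- function(pr, re) {
  s <- pr + re
  ifelse(s > 0, 2 * pr * re / s, 0)
}

#' Aggregate per-class metrics into a classification report
#'
#' Builds the full report from per-class precision/recall (and optionally
#' externally supplied F1 values): macro averages are unweighted means,
#' weighted averages are support-weighted means, and overall accuracy is
#' taken from the confusion matrix when one is supplied.
#'
#' @param per_class A data.frame as returned by [precision_recall()]
#'   (columns `class`, `precision`, `recall`, `support`; `f1` optional and
#'   computed via [f1_score()] when absent).
#' @param accuracy Overall accuracy in percent, or `NA`.
#' @return An object of class `sac_class_report`: list with `per_class`
#'   (now including `f1`), `accuracy`, `macro` and `weighted` rows, and
#'   `total_support`.
#' @export
aggregate_report <- function(per_class, accuracy = NA_real_) {
  stopifnot(all(c("class", "precision", "recall", "support") %in%
                  names(per_class)))
  if (is.null(per_class$f1)) {
    per_class$f1 <- f1_score(per_class$precision, per_class$recall)
  }
  w <- per_class$support / sum(per_class$support)
  macro <- c(precision = mean(per_class$precision),
             recall = mean(per_class$recall),
             f1 = mean(per_class$f1))
  weighted <- c(precision = sum(w * per_class$precision),
                recall = sum(w * per_class$recall),
                f1 = sum(w * per_class$f1))
  structure(list(per_class = per_class,
                 accuracy = accuracy,
                 macro = macro,
                 weighted = weighted,
                 total_support = sum(per_class$support)),
            class = "sac_class_report")
}

#' Classification report from a confusion matrix
#'
#' Convenience wrapper: [precision_recall()] + [f1_score()] +
#' [aggregate_report()] + [accuracy()].
#'
#' @param cm A confusion matrix (rows = truth, columns = predicted).
#' @return An `sac_class_report`.
#' @export
classification_report <- function(cm) {
  aggregate_report(precision_recall(cm), accuracy = accuracy(cm))
}

#' @export
print.sac_class_report <- function(x, digits = 2, ...) {
  pc <- x$per_class
  wid <- max(nchar(c(pc$class, "Weighted Avg"))) + 2
  fmt <- paste0("%-", wid, "s %8s %8s %8s %8s\n")
  cat(sprintf(fmt, "Class", "Pr(%)", "Re(%)", "F1(%)", "Support"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf(fmt, pc$class[i],
                formatC(pc$precision[i], digits = digits, format = "f"),
                formatC(pc$recall[i], digits = digits, format = "f"),
                formatC(pc$f1[i], digits = digits, format = "f"),
                pc$support[i]))
  }
  if (!is.na(x$accuracy)) {
    cat(sprintf(fmt, "Overall Acc", "", "",
                formatC(x$accuracy, digits = digits, format = "f"),
                x$total_support))
  }
  cat(sprintf(fmt, "Macro Avg",
              formatC(x$macro["precision"], digits = digits, format = "f"),
              formatC(x$macro["recall"], digits = digits, format = "f"),
              formatC(x$macro["f1"], digits = digits, format = "f"),
              x$total_support))
  cat(sprintf(fmt, "Weighted Avg",
              formatC(x$weighted["precision"], digits = digits, format = "f"),
              formatC(x$weighted["recall"], digits = digits, format = "f"),
              formatC(x$weighted["f1"], digits = digits, format = "f"),
              x$total_support))
  invisible(x)
}

#' Serialize a classification report
#'
#' @param report An `sac_class_report`.
#' @param path Output file; format by extension (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(per_class = report$per_class,
           accuracy = report$accuracy,
           macro = as.list(report$macro),
           weighted = as.list(report$weighted),
           total_support = report$total_support),
      path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    pc <- report$per_class[, c("class", "precision", "recall", "f1", "support")]
    extra <- data.frame(
      class = c("overall_accuracy", "macro_avg", "weighted_avg"),
      precision = c(NA, report$macro["precision"], report$weighted["precision"]),
      recall = c(NA, report$macro["recall"], report$weighted["recall"]),
      f1 = c(report$accuracy, report$macro["f1"], report$weighted["f1"]),
      support = rep(report$total_support, 3))
    utils::write.csv(rbind(pc, extra), path, row.names = FALSE)
  } else {
    stop("unsupported report format: .", ext)
  }
  invisible(path)
}

#' Write a confusion matrix as labeled CSV
#'
#' @param cm An `sac_confusion` matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  m <- as.matrix(cm)
  df <- data.frame(truth = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
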