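# Confusion-matrix metrics for the five-class beat classifier.

#' Build a 5x5 confusion matrix
#'
#' Rows are the predicted class, columns the original (true) class, in the
#' fixed order N, S, V, F, Q.
#'
#' @param pred Character vector of predicted labels.
#' @param truth Character vector of true labels, same length.
#' @return 5x5 integer matrix with dimnames `predicted` x `original`.
#' @export
confusion_matrix5 <- function(pred, truth) {
  cls <- beat_classes()
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (!all(pred %in% cls) || !all(truth %in% cls)) {
    stop("labels must be among ", paste(cls, collapse = ","))
  }
  cm <- table(factor(pred, levels = cls), factor(truth, levels = cls))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(predicted = cls, original = cls))
  cm
}

#' Per-class TP/TN/FP/FN counts
#'
#' For a one-vs-rest view of class `cls`: TP is the diagonal entry, FP the
#' rest of its predicted row, FN the rest of its original column, TN
#' everything else; the four always sum to the matrix total.
#'
#' @param cm 5x5 confusion matrix (rows predicted, columns original).
#' @param cls Class label.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
per_class_counts <- function(cm, cls) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  i <- match(cls, rownames(cm))
  if (is.na(i)) stop("unknown class: ", cls)
  tp <- cm[i, i]
  fp <- sum(cm[i, ]) - tp
  fn <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

.ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as NA",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Full metric report from a confusion matrix
#'
#' Per class: sensitivity `TP/(TP+FN)`, positive predictive value
#' `TP/(TP+FP)`, specificity `TN/(TN+FP)`, two-class accuracy
#' `(TP+TN)/total` and F1 `2TP/(2TP+FP+FN)`. Overall: multi-class accuracy
#' `trace/total` and macro-F1 (unweighted mean of the per-class F1 scores).
#' Undefined ratios (zero denominators on degenerate data) are reported as
#' `NA` with a warning, never silently as 0. Raw ratios are returned; the
#' `table` element carries display percentages rounded to 2 decimals
#' (round-half-even).
#'
#' @param cm Confusion matrix from [confusion_matrix5()] (any square matrix
#'   with class dimnames works).
#' @return Object of class `metric_report`: list with `per_class` (data
#'   frame of raw ratios), `accuracy`, `macro_f1` and `table` (percentages).
#' @export
metric_report <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  cls <- rownames(cm)
  per <- data.frame(class = cls, Sen = NA_real_, Ppv = NA_real_,
                    Spec = NA_real_, Acc2 = NA_real_, F1 = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(cls)) {
    ct <- per_class_counts(cm, cls[k])
    per$Sen[k] <- .ratio(ct["TP"], ct["TP"] + ct["FN"], paste0("Sen[", cls[k], "]"))
    per$Ppv[k] <- .ratio(ct["TP"], ct["TP"] + ct["FP"], paste0("Ppv[", cls[k], "]"))
    per$Spec[k] <- .ratio(ct["TN"], ct["TN"] + ct["FP"], paste0("Spec[", cls[k], "]"))
    per$Acc2[k] <- (ct["TP"] + ct["TN"]) / total
    per$F1[k] <- .ratio(2 * ct["TP"], 2 * ct["TP"] + ct["FP"] + ct["FN"],
                        paste0("F1[", cls[k], "]"))
  }
  acc <- sum(diag(cm)) / total
  macro <- mean(per$F1)
  tab <- per
  tab[, -1] <- round(tab[, -1] * 100, 2)
  structure(list(per_class = per, accuracy = acc, macro_f1 = macro,
                 table = tab,
                 accuracy_pct = round(acc * 100, 2),
                 macro_f1_pct = round(macro * 100, 2)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%, macro-F1 %.2f%%\n", x$accuracy * 100,
              x$macro_f1 * 100))
  print(x$table, row.names = FALSE)
  invisible(x)
}
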