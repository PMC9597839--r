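#' Cross-tabulate clinical truth against predictions
#'
#' Builds the confusion table feeding the diagnostic test characteristics.
#' Rows are the clinical reference, columns the prediction, in the order of
#' \code{labels}. For a two-category table put the lame-positive label
#' first, so the cells read TP, FN / FP, TN.
#'
#' @param clinical,predicted character vectors of equal length.
#' @param labels category names fixing the row/column order; defaults to the
#'   sorted union of observed labels.
#' @return An object of class \code{confusion_table}: an integer matrix with
#'   dimnames \code{clinical} x \code{predicted}.
#' @export
tabulate_confusion <- function(clinical, predicted, labels = NULL) {
  if (length(clinical) != length(predicted)) {
    stop("clinical and predicted must have equal length")
  }
  if (is.null(labels)) labels <- sort(unique(c(clinical, predicted)))
  bad <- setdiff(unique(c(clinical, predicted)), labels)
  if (length(bad) > 0L) {
    stop("label(s) not covered by 'labels': ", paste(bad, collapse = ", "))
  }
  tab <- table(factor(clinical, levels = labels),
               factor(predicted, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(clinical = labels, predicted = labels))
  structure(m, class = c("confusion_table", "matrix"))
}

#' Build a 2x2 confusion table from its four counts
#'
#' @param tp,fp,fn,tn true positives, false positives, false negatives and
#'   true negatives.
#' @param labels category names, positive first.
#' @return A \code{confusion_table}.
#' @export
confusion_2x2 <- function(tp, fp, fn, tn, labels = c("lame", "sound")) {
  m <- matrix(as.integer(c(tp, fp, fn, tn)), nrow = 2L,
              dimnames = list(clinical = labels, predicted = labels))
  structure(m, class = c("confusion_table", "matrix"))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> clinical (rows) x predicted (columns)\n")
  print(unclass(x))
  invisible(x)
}

#' Diagnostic test characteristics of a 2x2 table
#'
#' Sensitivity (SE) is the proportion of clinically lame horses classified
#' lame; specificity (SP) the proportion of clinically sound horses
#' classified sound; accuracy (ACC) the proportion of all correct calls;
#' positive and negative predictive values (PPV, NPV) the proportions of
#' correct positive and negative calls. All are returned in percent, rounded
#' half away from zero to one decimal; a metric with a zero denominator is
#' \code{NA} rather than an error.
#'
#' @param t a 2x2 \code{confusion_table} with the positive category first.
#' @return Named numeric vector \code{c(SE, SP, ACC, PPV, NPV)} in percent.
#' @examples
#' test_characteristics(confusion_2x2(tp = 8, fp = 1, fn = 1, tn = 7))
#' @export
test_characteristics <- function(t) {
  stopifnot(inherits(t, "confusion_table"), all(dim(t) == 2L))
  tp <- t[1L, 1L]; fn <- t[1L, 2L]; fp <- t[2L, 1L]; tn <- t[2L, 2L]
  pct <- function(num, den) {
    if (den == 0L) NA_real_ else round_half_up(100 * num / den, 1)
  }
  c(SE = pct(tp, tp + fn),
    SP = pct(tn, tn + fp),
    ACC = pct(tp + tn, tp + fn + fp + tn),
    PPV = pct(tp, tp + fp),
    NPV = pct(tn, tn + fn))
}

#' Cohen's kappa of a square confusion table
#'
#' Chance-corrected agreement between the clinical reference and the
#' pipeline: \code{kappa = (Po - Pe) / (1 - Pe)} with observed agreement
#' \code{Po = trace/total} and expected agreement
#' \code{Pe = sum(row_i * col_i) / total^2}. Returns \code{NA} when the
#' margins force \code{Pe = 1}.
#'
#' @param t a square \code{confusion_table}.
#' @return Kappa in [-1, 1], unrounded.
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "confusion_table"), nrow(t) == ncol(t))
  total <- sum(t)
  if (total == 0L) stop("empty confusion table")
  po <- sum(diag(t)) / total
  pe <- sum(rowSums(t) * colSums(t)) / total^2
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Overall accuracy of a square confusion table
#'
#' @param t a square \code{confusion_table}.
#' @return Percent of correctly classified horses, rounded half away from
#'   zero to one decimal.
#' @export
overall_accuracy <- function(t) {
  stopifnot(inherits(t, "confusion_table"), nrow(t) == ncol(t))
  total <- sum(t)
  if (total == 0L) stop("empty confusion table")
  round_half_up(100 * sum(diag(t)) / total, 1)
}
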