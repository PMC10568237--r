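# Confusion counts and summary statistics, AFIB = positive class.

#' Confusion counts
#'
#' Either supply the four counts directly or derive them from parallel
#' truth/prediction label vectors with AFIB as the positive class.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @param truth,predicted alternatively, character vectors of "NSR"/"AFIB"
#'   labels; predictions other than "AFIB" count as negative.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                             truth = NULL, predicted = NULL) {
  if (!is.null(truth)) {
    stopifnot(length(truth) == length(predicted))
    pos_t <- truth == "AFIB"
    pos_p <- predicted == "AFIB"
    tp <- sum(pos_t & pos_p); fp <- sum(!pos_t & pos_p)
    tn <- sum(!pos_t & !pos_p); fn <- sum(pos_t & !pos_p)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("            predicted\n")
  cat("truth        AFIB   NSR\n")
  cat(sprintf("  AFIB  %9d %5d\n", x$tp, x$fn))
  cat(sprintf("  NSR   %9d %5d\n", x$fp, x$tn))
  invisible(x)
}

#' Accuracy, precision, recall and F1 as percentages
#'
#' `accuracy = 100 (TP + TN) / total`, `precision = 100 TP / (TP + FP)`,
#' `recall = 100 TP / (TP + FN)`, `f1 = 2 P R / (P + R)`. A
#' zero-denominator branch (e.g. an all-negative dataset, where neither
#' precision nor a full confusion summary is meaningful) yields `NA` with
#' a warning rather than a silent 0.
#'
#' @param counts a [confusion_counts()].
#' @param digits round the percentages to this many decimals; `NULL` for
#'   full precision.
#' @return named list: `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
score_metrics <- function(counts, digits = NULL) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  acc <- 100 * (counts$tp + counts$tn) / total
  prec <- if (counts$tp + counts$fp == 0) {
    warning("precision undefined: no positive predictions", call. = FALSE)
    NA_real_
  } else 100 * counts$tp / (counts$tp + counts$fp)
  rec <- if (counts$tp + counts$fn == 0) {
    warning("recall undefined: no positive cases", call. = FALSE)
    NA_real_
  } else 100 * counts$tp / (counts$tp + counts$fn)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else {
    2 * prec * rec / (prec + rec)
  }
  out <- list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  if (!is.null(digits)) out <- lapply(out, round, digits = digits)
  out
}

#' Write a metrics report
#'
#' @param counts a [confusion_counts()].
#' @param path output file; `.json` or `.csv` by extension.
#' @return the report list, invisibly.
#' @export
write_metrics <- function(counts, path) {
  m <- suppressWarnings(score_metrics(counts))
  report <- c(unclass(counts), m)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(report)
}
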