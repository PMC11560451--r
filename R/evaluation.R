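#' Confusion-matrix metrics
#'
#' Segment-level classification metrics with ictal as the positive class:
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 `2*prec*rec/(prec+rec)` with `prec = TP/(TP+FP)`.
#' When a metric's denominator is empty (single-class labels, no positive
#' predictions) it is reported as `NA` and flagged, never silently as 0.
#'
#' @param labels 0/1 true labels.
#' @param predictions 0/1 predicted labels.
#' @return A `metric_report` (without `auc`): list with counts `tp`, `tn`,
#'   `fp`, `fn`, metrics `acc`, `sens`, `spec`, `f1`, and `undefined`, the
#'   names of any undefined metrics.
#' @export
confusion_metrics <- function(labels, predictions) {
  abort_if(length(labels) != length(predictions),
           "labels and predictions must have equal length")
  abort_if(!all(labels %in% 0:1) || !all(predictions %in% 0:1),
           "labels and predictions must be 0/1")
  tp <- sum(labels == 1L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  und <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { und <- c(und, "sens"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { und <- c(und, "spec"); NA_real_ }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens)
  else { und <- c(und, "f1"); NA_real_ }
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = (tp + tn) / length(labels),
                 sens = sens, spec = spec, f1 = f1, auc = NA_real_,
                 undefined = und),
            class = "metric_report")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a random
#' positive scores above a random negative, with ties contributing one half.
#' Equivalent to the trapezoidal area under the ROC curve and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param labels 0/1 true labels (both classes must be present).
#' @param scores Positive-class scores.
#' @return AUC in `[0, 1]`, or flagged `NA` for single-class labels.
#' @export
auc <- function(labels, scores) {
  abort_if(length(labels) != length(scores),
           "labels and scores must have equal length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: labels contain a single class")
    return(NA_real_)
  }
  r <- rank(scores)                       # average ranks: ties count 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Combined metric report
#'
#' @param labels,predictions As in [confusion_metrics()].
#' @param scores Optional positive-class scores for AUC.
#' @return A `metric_report` with `auc` filled in when scores are given.
#' @export
metric_report <- function(labels, predictions, scores = NULL) {
  rep <- confusion_metrics(labels, predictions)
  if (!is.null(scores)) {
    both <- sum(labels == 1L) > 0L && sum(labels == 0L) > 0L
    rep$auc <- if (both) auc(labels, scores) else NA_real_
    if (!both) rep$undefined <- c(rep$undefined, "auc")
  }
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  acc %.4f  sens %s  spec %s  f1 %s  auc %s\n",
              x$tp + x$tn + x$fp + x$fn, x$acc,
              fmt_or_na(x$sens), fmt_or_na(x$spec), fmt_or_na(x$f1),
              fmt_or_na(x$auc)))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' Per-case metric table with a mean row
#'
#' @param reports Named list of `metric_report`s (one per fold or patient).
#' @return data.frame with fractional metrics per case plus a `mean` row
#'   (column-wise mean over defined values).
#' @export
metrics_table <- function(reports) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(case = nm, n = r$tp + r$tn + r$fp + r$fn,
               acc = r$acc, sens = r$sens, spec = r$spec, f1 = r$f1,
               auc = r$auc)
  }))
  mean_row <- data.frame(case = "mean", n = sum(df$n),
                         acc = mean(df$acc, na.rm = TRUE),
                         sens = mean(df$sens, na.rm = TRUE),
                         spec = mean(df$spec, na.rm = TRUE),
                         f1 = mean(df$f1, na.rm = TRUE),
                         auc = mean(df$auc, na.rm = TRUE))
  rbind(df, mean_row)
}

#' Write a metric table
#'
#' CSV and Markdown emit percentages with two decimals (per-case rows plus the
#' mean row); JSON keeps full-precision fractions.
#'
#' @param tab data.frame from [metrics_table()].
#' @param path Output file.
#' @return `path` invisibly (`format_metrics_markdown()` returns a character
#'   vector of lines).
#' @export
write_metrics_csv <- function(tab, path) {
  out <- tab
  for (cl in c("acc", "sens", "spec", "f1", "auc"))
    out[[cl]] <- sprintf("%.2f", 100 * tab[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_metrics_json <- function(tab, path) {
  jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
format_metrics_markdown <- function(tab) {
  hdr <- "| Case | Acc (%) | Sens (%) | Spec (%) | F1 (%) | AUC (%) |"
  sep <- "|---|---|---|---|---|---|"
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    v <- vapply(c("acc", "sens", "spec", "f1", "auc"), function(cl) {
      x <- tab[[cl]][i]
      if (is.na(x)) "NA" else sprintf("%.2f", 100 * x)
    }, "")
    paste0("| ", tab$case[i], " | ", paste(v, collapse = " | "), " |")
  }, "")
  c(hdr, sep, rows)
}
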