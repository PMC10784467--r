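#' Classification metrics from predicted and true labels
#'
#' PAD is the positive class. Accuracy is the proportion of correctly
#' classified instances; precision TP/(TP+FP); recall TP/(TP+FN);
#' F1 the harmonic mean of precision and recall. Ratios with a zero
#' denominator are reported as missing (`NA`), not as 0.
#'
#' @param truth character vector of `"PAD"` / `"healthy"`.
#' @param pred character vector of predicted labels, same length.
#' @param level `"subject"` or `"window"`, recorded in the report.
#' @param path optional path id tag.
#' @return an `eval_report` object: confusion counts plus metrics.
#' @export
eval_report <- function(truth, pred, level = "subject", path = NA) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) == 0) {
    abort("empty test set.", class = "gaitdx_data_error")
  }
  tp <- sum(truth == "PAD" & pred == "PAD")
  fp <- sum(truth == "healthy" & pred == "PAD")
  fn <- sum(truth == "PAD" & pred == "healthy")
  tn <- sum(truth == "healthy" & pred == "healthy")
  structure(
    list(confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
         metrics = metrics_from_confusion(tp, fp, fn, tn),
         level = level, path = path, n = length(truth)),
    class = "eval_report")
}

metrics_from_confusion <- function(tp, fp, fn, tn) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(accuracy = div(tp + tn, tp + fp + fn + tn),
    precision = precision, recall = recall, f1 = f1)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> level=%s%s, n=%d\n", x$level,
              if (!is.na(x$path)) paste0(", path=", x$path) else "", x$n))
  cat(sprintf("  confusion (PAD positive): TP=%d FP=%d FN=%d TN=%d\n",
              x$confusion["TP"], x$confusion["FP"],
              x$confusion["FN"], x$confusion["TN"]))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f | precision %s | recall %s | F1 %s\n",
              m["accuracy"],
              formatC(m["precision"], digits = 3, format = "f"),
              formatC(m["recall"], digits = 3, format = "f"),
              formatC(m["f1"], digits = 3, format = "f")))
  invisible(x)
}
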