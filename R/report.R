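#' Evaluation report for a set of models
#'
#' Computes the configured metric panel for each prediction against one
#' ground truth and returns a models-by-metrics table, optionally written as
#' CSV and aligned plain text.
#'
#' @param preds List of `model_prediction` objects.
#' @param truth A `ground_truth`.
#' @param metric_names Metric panel (default [default_metric_set()]).
#' @param csv_path,txt_path Optional output paths.
#' @return A data frame with a `model` column followed by one column per
#'   metric.
#' @export
eval_report <- function(preds, truth, metric_names = default_metric_set(),
                        csv_path = NULL, txt_path = NULL) {
  if (inherits(preds, "model_prediction")) preds <- list(preds)
  rows <- lapply(preds, function(p) {
    mv <- metric_vector(p, truth, metric_names)
    cbind(data.frame(model = p$model_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(mv))))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("model", metric_names)
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    fmt <- out
    fmt[metric_names] <- lapply(fmt[metric_names], function(v) sprintf("%.4f", v))
    widths <- pmax(nchar(names(fmt)),
                   vapply(fmt, function(col) max(nchar(as.character(col))),
                          numeric(1)))
    pad <- function(v, w) formatC(as.character(v), width = w)
    lines <- c(
      paste(mapply(pad, names(fmt), widths), collapse = "  "),
      vapply(seq_len(nrow(fmt)), function(i)
        paste(mapply(pad, as.character(unlist(fmt[i, ])), widths),
              collapse = "  "), character(1)))
    writeLines(lines, txt_path)
  }
  out
}
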