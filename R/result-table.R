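#' Long-format result table
#'
#' A uniform row format for study outputs: one row per entity (neuron,
#' electrode, pair or group), epoch and metric. Metric names are validated
#' against a registered vocabulary so downstream consumers can rely on
#' spelling. Serialization is tab-separated with fixed column order and
#' round-trips losslessly at 1e-6 precision.
#'
#' @param entity_id character entity identifiers.
#' @param epoch epoch names (or `NA`).
#' @param metric metric names from [result_metrics()].
#' @param value numeric values.
#' @param p_value optional p-values.
#' @param flag optional character flags.
#' @return A tibble of class `result_table`.
#' @export
result_table <- function(entity_id, epoch, metric, value,
                         p_value = NA_real_, flag = NA_character_) {
  bad <- setdiff(unique(metric), result_metrics())
  if (length(bad) > 0)
    stop("unregistered metric name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- tibble::tibble(
    entity_id = as.character(entity_id), epoch = as.character(epoch),
    metric = as.character(metric), value = as.numeric(value),
    p_value = as.numeric(p_value), flag = as.character(flag)
  )
  class(out) <- c("result_table", class(out))
  out
}

#' @rdname result_table
#' @export
result_metrics <- function() {
  c("rate_hz", "baseline_hz", "delta_hz", "ari_ms", "ari_shortening_ms",
    "st_mv", "dor_ms2", "si", "c_obs", "null_mean", "follow_fraction",
    "latency_mean_ms", "latency_sd_ms", "n_significant",
    "si_sum_significant", "count")
}

#' @rdname result_table
#' @param x a `result_table`.
#' @param path file path (TSV).
#' @export
write_result_table <- function(x, path) {
  df <- as.data.frame(x)[c("entity_id", "epoch", "metric", "value",
                           "p_value", "flag")]
  df$value <- sprintf("%.6f", df$value)
  df$p_value <- ifelse(is.na(df$p_value), "NA", sprintf("%.6g", df$p_value))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname result_table
#' @export
read_result_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "numeric", "character", "character"))
  df$p_value <- suppressWarnings(as.numeric(df$p_value))
  result_table(df$entity_id, df$epoch, df$metric, df$value, df$p_value,
               df$flag)
}
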