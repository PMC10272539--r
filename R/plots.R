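#' Compact electrogram timeline
#'
#' A short per-epoch timeline for electrogram synthesis and analysis:
#' consecutive blocks of `n_beats` beats for `baseline_pre`, `lad_pre`,
#' `baseline_post` and `lad_post`. Cardiac metrics are per-beat, so a
#' handful of beats per state carries the same information as minutes of
#' record.
#'
#' @param n_beats beats per epoch.
#' @param rr_interval_s beat period (s).
#' @return A [protocol_timeline()].
#' @export
compact_egm_timeline <- function(n_beats = 20, rr_interval_s = 0.6) {
  len <- n_beats * rr_interval_s
  protocol_timeline(list(
    baseline_pre = c(0, len), lad_pre = c(len, 2 * len),
    baseline_post = c(2 * len, 3 * len), lad_post = c(3 * len, 4 * len)
  ))
}

#' Plot an ARI map
#'
#' Tile map of per-electrode ARI, electrodes arranged on a grid
#' column-major. Ischemic-zone electrodes can be outlined via `mask`.
#'
#' @param map a [compute_ari()] tibble.
#' @param ncol grid columns (default 8).
#' @param mask optional electrode ids to outline.
#' @return A ggplot object.
#' @export
plot_ari_map <- function(map, ncol = 8, mask = NULL) {
  df <- dplyr::mutate(map,
    col = (.data$electrode_id - 1) %/% ncol + 1,
    row = (.data$electrode_id - 1) %% ncol + 1,
    in_mask = .data$electrode_id %in% (mask %||% integer(0)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$ari_ms)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = df[df$in_mask, ], fill = NA,
                       color = "red", linewidth = 1) +
    ggplot2::scale_fill_viridis_c(name = "ARI (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot binned firing-rate series
#'
#' @param rs a [rate_series()] tibble (tabular form, with `neuron_id`).
#' @param timeline optional [protocol_timeline()]; epoch boundaries are
#'   drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_rate_series <- function(rs, timeline = NULL) {
  p <- ggplot2::ggplot(rs, ggplot2::aes(.data$bin_start, .data$rate_hz)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~neuron_id, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "firing rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(timeline))
    p <- p + ggplot2::geom_vline(xintercept = timeline$epochs$start,
                                 linetype = "dashed", color = "grey50")
  p
}

#' Plot response deltas across epochs
#'
#' Box plot of per-neuron firing-rate deltas by epoch, the study's central
#' comparison (occlusion and reperfusion, before vs after stimulation).
#'
#' @param deltas delta table from [run_study()] / [response_delta()].
#' @return A ggplot object.
#' @export
plot_response_deltas <- function(deltas) {
  lv <- intersect(c("lad_pre", "rep_pre", "lad_post", "rep_post"),
                  unique(deltas$epoch))
  ggplot2::ggplot(deltas,
                  ggplot2::aes(factor(.data$epoch, levels = lv),
                               .data$delta_hz)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "rate change vs baseline (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang %||%
NULL
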