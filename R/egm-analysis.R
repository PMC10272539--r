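#' Smoothed derivative of a sampled waveform
#'
#' Least-squares local-polynomial (Savitzky-Golay, order 2) first
#' derivative, in mV/s. Used by the activation/repolarization detectors.
#'
#' @param x numeric samples (mV).
#' @param fs sampling rate (Hz).
#' @param window_ms smoothing window width in ms (default 5).
#' @return Numeric vector of d(x)/dt, same length as `x`.
#' @keywords internal
sg_derivative <- function(x, fs, window_ms = 5) {
  n <- max(3L, round(window_ms * fs / 1000))
  if (n %% 2 == 0) n <- n + 1L
  if (n >= length(x)) n <- if (length(x) %% 2 == 0) length(x) - 1L else length(x) - 2L
  signal::sgolayfilt(x, p = 2, n = n, m = 1) * fs
}

#' Detect activation time on a unipolar electrogram beat
#'
#' Activation time (AT) is the instant of steepest negative slope
#' (minimum dV/dt) inside the QRS search window — the standard criterion
#' for local activation on unipolar electrograms. Ties take the earliest
#' sample. Segments whose peak-to-peak amplitude is below
#' `min_amplitude_mv` are flagged undefined (`NA`).
#'
#' @param segment numeric vector, one beat's samples in mV.
#' @param fs sampling rate (Hz).
#' @param search_window `c(start, end)` seconds from segment start; `NULL`
#'   searches the whole segment.
#' @param deriv_window_ms derivative smoothing width (ms).
#' @param min_amplitude_mv noise floor for the amplitude gate.
#' @return AT in seconds from segment start, or `NA` if undefined.
#' @export
detect_activation_time <- function(segment, fs, search_window = NULL,
                                   deriv_window_ms = 5,
                                   min_amplitude_mv = 0.05) {
  if (diff(range(segment)) < min_amplitude_mv) return(NA_real_)
  d <- sg_derivative(segment, fs, deriv_window_ms)
  tt <- (seq_along(segment) - 1) / fs
  keep <- if (is.null(search_window)) rep(TRUE, length(tt))
          else tt >= search_window[1] & tt <= search_window[2]
  if (!any(keep)) stop("empty search window", call. = FALSE)
  dk <- d[keep]
  dmin <- min(dk)
  idx <- which(keep)[which(dk <= dmin + 1e-9 * max(1, abs(dmin)))[1]]
  tt[idx]
}

#' Detect repolarization time on a unipolar electrogram beat
#'
#' Repolarization time (RT) follows the Wyatt convention: the instant of
#' maximum dV/dt inside the T-wave window, irrespective of T-wave polarity.
#' The default derivative smoothing is wider than for activation detection
#' because the T wave is a much slower deflection.
#'
#' @inheritParams detect_activation_time
#' @param t_window `c(start, end)` seconds from segment start; must exclude
#'   the QRS.
#' @param deriv_window_ms derivative smoothing width (ms; default 25).
#' @return RT in seconds from segment start, or `NA` if undefined.
#' @export
detect_repolarization_time <- function(segment, fs, t_window,
                                       deriv_window_ms = 25,
                                       min_amplitude_mv = 0.05) {
  if (missing(t_window) || is.null(t_window) || diff(t_window) <= 0)
    stop("`t_window` must be a non-empty interval", call. = FALSE)
  if (diff(range(segment)) < min_amplitude_mv) return(NA_real_)
  d <- sg_derivative(segment, fs, deriv_window_ms)
  tt <- (seq_along(segment) - 1) / fs
  keep <- tt >= t_window[1] & tt <= t_window[2]
  if (!any(keep)) stop("`t_window` outside segment", call. = FALSE)
  dk <- d[keep]
  dmax <- max(dk)
  idx <- which(keep)[which(dk >= dmax - 1e-9 * max(1, abs(dmax)))[1]]
  tt[idx]
}

#' Measure ST-segment deviation on one beat
#'
#' Mean amplitude over the ST window minus mean amplitude over the
#' isoelectric (pre-QRS) window; depression is reported with negative sign.
#'
#' @inheritParams detect_activation_time
#' @param st_window,iso_window `c(start, end)` seconds from segment start.
#' @return ST deviation in mV.
#' @export
measure_st_elevation <- function(segment, fs, st_window = c(0.095, 0.160),
                                 iso_window = c(0, 0.012)) {
  if (st_window[1] < iso_window[2] && iso_window[1] < st_window[2])
    stop("ST and isoelectric windows overlap", call. = FALSE)
  tt <- (seq_along(segment) - 1) / fs
  st <- segment[tt >= st_window[1] & tt < st_window[2]]
  iso <- segment[tt >= iso_window[1] & tt < iso_window[2]]
  if (length(st) == 0 || length(iso) == 0)
    stop("measurement window outside segment", call. = FALSE)
  mean(st) - mean(iso)
}

#' Per-beat electrogram measurements
#'
#' Splits a multichannel record at its beat marks and measures activation
#' time, repolarization time, ARI and ST deviation on every electrode and
#' beat. Window defaults match a beat template with activation near 40 ms
#' and repolarization of 240–360 ms; override them for other morphologies.
#'
#' @param egm an [egm_set()] with beat marks.
#' @param qrs_window,t_window,st_window,iso_window measurement windows in
#'   seconds from beat onset.
#' @param deriv_window_ms,t_deriv_window_ms derivative smoothing for the
#'   QRS and T wave respectively (ms).
#' @param min_amplitude_mv amplitude gate; beats below it are flagged.
#' @return A tibble with one row per electrode and beat: `electrode_id`,
#'   `beat_index`, `onset_s`, `at_s`, `rt_s` (absolute seconds), `ari_ms`,
#'   `st_mv`, `valid`.
#' @export
measure_beats <- function(egm, qrs_window = c(0, 0.120),
                          t_window = c(0.200, 0.500),
                          st_window = c(0.095, 0.160),
                          iso_window = c(0, 0.012),
                          deriv_window_ms = 5, t_deriv_window_ms = 25,
                          min_amplitude_mv = 0.05) {
  stopifnot(inherits(egm, "egm_set"))
  if (is.null(egm$beat_marks) || length(egm$beat_marks) == 0)
    stop("`egm` carries no beat marks", call. = FALSE)
  fs <- egm$fs
  nsamp <- ncol(egm$samples)
  marks <- egm$beat_marks
  ends <- c(marks[-1], nsamp / fs)
  out <- vector("list", length(egm$electrode_ids))
  for (e in seq_along(egm$electrode_ids)) {
    x <- egm$samples[e, ]
    at <- rt <- st <- rep(NA_real_, length(marks))
    for (b in seq_along(marks)) {
      i0 <- round(marks[b] * fs) + 1
      i1 <- min(round(ends[b] * fs), nsamp)
      seg <- x[i0:i1]
      at[b] <- detect_activation_time(seg, fs, qrs_window, deriv_window_ms,
                                      min_amplitude_mv)
      if (!is.na(at[b])) {
        rt[b] <- detect_repolarization_time(seg, fs, t_window,
                                            t_deriv_window_ms, min_amplitude_mv)
        st[b] <- measure_st_elevation(seg, fs, st_window, iso_window)
      }
    }
    out[[e]] <- tibble::tibble(
      electrode_id = egm$electrode_ids[e], beat_index = seq_along(marks),
      onset_s = marks, at_s = marks + at, rt_s = marks + rt,
      ari_ms = (rt - at) * 1000, st_mv = st,
      valid = !is.na(at) & !is.na(rt) & (rt > at)
    )
  }
  dplyr::bind_rows(out)
}

#' Epoch ARI map
#'
#' Per-electrode mean activation recovery interval over the valid beats of
#' an epoch. Electrodes with under `min_valid_frac` valid beats are kept
#' but flagged; electrodes with no valid beat are dropped with a warning.
#'
#' @param beats a [measure_beats()] tibble.
#' @param epoch optional `c(start, end)` seconds; keeps beats whose onset
#'   falls in the half-open window.
#' @param min_valid_frac validity threshold for flagging (default 0.5).
#' @return A tibble `electrode_id`, `ari_ms`, `n_beats`, `n_valid`,
#'   `flagged`.
#' @export
compute_ari <- function(beats, epoch = NULL, min_valid_frac = 0.5) {
  if (!is.null(epoch)) beats <- beats[in_window_(beats$onset_s, epoch), ]
  map <- beats |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(
      ari_ms = mean(.data$ari_ms[.data$valid]),
      n_beats = dplyr::n(), n_valid = sum(.data$valid),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_valid < min_valid_frac * .data$n_beats)
  dropped <- map$electrode_id[map$n_valid == 0]
  if (length(dropped) > 0) {
    warning("electrode(s) with no valid beats excluded: ",
            paste(dropped, collapse = ", "))
    map <- map[map$n_valid > 0, ]
  }
  map
}

#' Ischemic-zone mask from ST deviation
#'
#' Electrodes whose ST deviation during ischemia exceeds the threshold
#' (strictly) form the ischemic zone.
#'
#' @param st a data frame with `electrode_id` and `st_mv` (e.g. per-epoch
#'   means of a [measure_beats()] table).
#' @param threshold_mv mV criterion (default 0.1).
#' @return Integer vector of electrode ids.
#' @export
define_ischemic_zone <- function(st, threshold_mv = 0.1) {
  stopifnot(all(c("electrode_id", "st_mv") %in% names(st)))
  mask <- st$electrode_id[!is.na(st$st_mv) & st$st_mv > threshold_mv]
  if (length(mask) == 0)
    warning("no electrodes exceed the ST threshold; empty ischemic zone")
  as.integer(mask)
}

#' ARI shortening over the ischemic zone
#'
#' Mean over the masked electrodes of (ischemia ARI - baseline ARI);
#' negative values indicate shortening, the sympathoexcitation signature.
#'
#' @param map_baseline,map_ischemia ARI maps from [compute_ari()].
#' @param mask electrode ids (the ischemic zone).
#' @return Shortening in ms (scalar).
#' @export
ari_shortening <- function(map_baseline, map_ischemia, mask) {
  if (length(mask) == 0) stop("empty ischemic mask", call. = FALSE)
  b <- map_baseline[match(mask, map_baseline$electrode_id), "ari_ms", drop = TRUE]
  i <- map_ischemia[match(mask, map_ischemia$electrode_id), "ari_ms", drop = TRUE]
  if (anyNA(b) || anyNA(i))
    stop("mask electrodes missing from one of the maps", call. = FALSE)
  mean(i - b)
}

#' Global dispersion of repolarization
#'
#' Sample variance (n - 1 denominator), across electrodes, of the
#' per-electrode mean repolarization metric: either repolarization time
#' relative to beat onset (`"rt"`, default) or ARI (`"ari"`). Units ms^2.
#' Larger dispersion marks greater repolarization heterogeneity and
#' arrhythmogenic risk.
#'
#' @param beats a [measure_beats()] tibble.
#' @param epoch optional `c(start, end)` restriction (half-open, by onset).
#' @param metric `"rt"` or `"ari"`.
#' @return A one-row tibble: `metric`, `dor_ms2`, `n_electrodes`.
#' @export
compute_dor <- function(beats, epoch = NULL, metric = c("rt", "ari")) {
  metric <- match.arg(metric)
  if (!is.null(epoch)) beats <- beats[in_window_(beats$onset_s, epoch), ]
  beats <- beats[beats$valid, ]
  per <- beats |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(
      value = if (metric == "rt") mean((.data$rt_s - .data$onset_s) * 1000)
              else mean(.data$ari_ms),
      .groups = "drop"
    )
  if (nrow(per) < 2)
    stop("dispersion of repolarization needs at least 2 electrodes",
         call. = FALSE)
  tibble::tibble(metric = metric, dor_ms2 = var(per$value),
                 n_electrodes = nrow(per))
}
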