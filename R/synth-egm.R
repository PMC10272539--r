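#' Synthetic electrogram configuration
#'
#' Describes a sock-electrode recording with known per-electrode activation
#' time (AT) and repolarization time (RT). Each beat is an analytic
#' template: the QRS is a Gaussian-derivative wave whose steepest negative
#' slope falls exactly at the true AT, and the T wave is a Gaussian bump
#' placed so its steepest positive slope falls exactly at the true RT
#' (whatever the T polarity). Ground truth is therefore exact by
#' construction. During ischemia epochs, electrodes in `ischemic_mask`
#' receive an ST-segment shift (raised-cosine edges, so the shift never
#' introduces slopes that compete with the QRS or T wave) and their RT is
#' advanced by `ari_shortening_ms`.
#'
#' @param n_electrodes number of electrodes (default 56, a sock array).
#' @param fs sampling rate in Hz; must be at least 500.
#' @param rr_interval_s beat period in seconds.
#' @param n_beats number of beats to synthesise; `NULL` fills the timeline.
#' @param at_ms,rt_ms true AT / RT offsets from beat onset in ms, recycled
#'   per electrode; `NULL` draws AT uniformly on 35–50 ms and RT on
#'   320–360 ms (integer milliseconds, so truth lies on the 1 kHz sample
#'   grid) under `seed`.
#' @param ischemic_mask electrode ids receiving the ischemic phenotype
#'   (default: the first quarter of the array).
#' @param st_shift_mv ST-segment deviation applied to ischemic electrodes
#'   during ischemia epochs (mV; negative values give ST depression).
#' @param ari_shortening_ms RT advance applied during ischemia epochs (ms).
#' @param noise_sd_mv additive Gaussian noise SD (mV).
#' @param t_polarity +1 for upright, -1 for inverted T waves, recycled per
#'   electrode.
#' @param qrs_amp_mv,qrs_sd_ms,t_amp_mv,t_sd_ms template shape: QRS peak
#'   amplitude and Gaussian width, T-wave amplitude and width.
#' @param seed RNG seed for AT/RT draws and noise.
#' @return A list of class `synth_egm_config`.
#' @export
synth_egm_config <- function(n_electrodes = 56, fs = 1000, rr_interval_s = 0.6,
                             n_beats = NULL, at_ms = NULL, rt_ms = NULL,
                             ischemic_mask = seq_len(ceiling(n_electrodes / 4)),
                             st_shift_mv = 0.2, ari_shortening_ms = 100,
                             noise_sd_mv = 0.05, t_polarity = 1,
                             qrs_amp_mv = 1, qrs_sd_ms = 6,
                             t_amp_mv = 0.5, t_sd_ms = 25, seed = NULL) {
  if (fs < 500) stop("`fs` must be >= 500 Hz", call. = FALSE)
  if (!is.null(at_ms)) at_ms <- rep_len(at_ms, n_electrodes)
  if (!is.null(rt_ms)) rt_ms <- rep_len(rt_ms, n_electrodes)
  if (!is.null(at_ms) && !is.null(rt_ms) && any(at_ms >= rt_ms))
    stop("true AT must precede true RT on every electrode", call. = FALSE)
  rt_max <- if (is.null(rt_ms)) 360 else max(rt_ms)
  if (rr_interval_s * 1000 < rt_max + 4 * t_sd_ms + 20)
    stop("`rr_interval_s` too short for the beat template", call. = FALSE)
  structure(
    list(n_electrodes = n_electrodes, fs = fs, rr_interval_s = rr_interval_s,
         n_beats = n_beats, at_ms = at_ms, rt_ms = rt_ms,
         ischemic_mask = as.integer(ischemic_mask), st_shift_mv = st_shift_mv,
         ari_shortening_ms = ari_shortening_ms, noise_sd_mv = noise_sd_mv,
         t_polarity = rep_len(t_polarity, n_electrodes),
         qrs_amp_mv = qrs_amp_mv, qrs_sd_ms = qrs_sd_ms,
         t_amp_mv = t_amp_mv, t_sd_ms = t_sd_ms, seed = seed),
    class = "synth_egm_config"
  )
}

# one beat, sampled at times tt (seconds from beat onset)
egm_beat_template_ <- function(tt, at, rt, qrs_amp, qrs_sd, t_amp, t_sd,
                               t_pol, st_mv) {
  k <- qrs_amp * exp(0.5) / qrs_sd
  v <- -k * (tt - at) * exp(-(tt - at)^2 / (2 * qrs_sd^2))
  ct <- if (t_pol > 0) rt + t_sd else rt - t_sd
  v <- v + t_pol * t_amp * exp(-(tt - ct)^2 / (2 * t_sd^2))
  if (st_mv != 0) {
    ramp <- 0.02
    st_on <- at + 4 * qrs_sd
    st_off <- ct + 2 * t_sd
    prof <- numeric(length(tt))
    up <- tt >= st_on & tt < st_on + ramp
    prof[up] <- 0.5 * (1 - cos(pi * (tt[up] - st_on) / ramp))
    prof[tt >= st_on + ramp & tt < st_off] <- 1
    dn <- tt >= st_off & tt < st_off + ramp
    prof[dn] <- 0.5 * (1 + cos(pi * (tt[dn] - st_off) / ramp))
    v <- v + st_mv * prof
  }
  v
}

#' Generate synthetic electrograms with ground truth
#'
#' Synthesises a continuous multichannel unipolar electrogram record from a
#' [synth_egm_config()]. Beats start at multiples of the RR interval; a
#' beat takes the ischemic phenotype when its onset falls inside an epoch
#' whose name starts with `"lad"` and its electrode is in the ischemic
#' mask. Identical seeds give bit-identical output.
#'
#' @param cfg a [synth_egm_config()].
#' @param timeline a [protocol_timeline()]; ischemia epochs are those whose
#'   names start with `"lad"`.
#' @return A list with `egm` (an [egm_set()] with beat marks) and `truth`
#'   (tibble of `electrode_id`, `beat_index`, `onset_s`, `at_s`, `rt_s`,
#'   `ari_ms`, `st_mv`, `ischemic`).
#' @examples
#' tl <- protocol_timeline(list(baseline_pre = c(0, 12), lad_pre = c(12, 24)))
#' cfg <- synth_egm_config(n_electrodes = 2, noise_sd_mv = 0, seed = 1)
#' sim <- gen_electrograms(cfg, tl)
#' sim$egm
#' @export
gen_electrograms <- function(cfg, timeline) {
  stopifnot(inherits(cfg, "synth_egm_config"),
            inherits(timeline, "protocol_timeline"))
  with_seed_(cfg$seed, {
    fs <- cfg$fs
    spb <- round(cfg$rr_interval_s * fs)
    total <- max(timeline$epochs$end)
    nb <- if (is.null(cfg$n_beats)) floor(total * fs / spb) else cfg$n_beats
    if (nb < 1) stop("timeline too short for one beat", call. = FALSE)
    at <- if (is.null(cfg$at_ms)) sample(35:50, cfg$n_electrodes, TRUE) else cfg$at_ms
    rt <- if (is.null(cfg$rt_ms)) sample(320:360, cfg$n_electrodes, TRUE) else cfg$rt_ms
    if (any(at >= rt)) stop("true AT must precede true RT", call. = FALSE)
    at <- at / 1000; rt <- rt / 1000
    onsets <- (seq_len(nb) - 1) * spb / fs
    lad <- timeline$epochs[grepl("^lad", timeline$epochs$epoch), , drop = FALSE]
    isch_beat <- vapply(onsets, function(o)
      any(o >= lad$start & o < lad$end), logical(1))
    tt <- (seq_len(spb) - 1) / fs
    qs <- cfg$qrs_sd_ms / 1000; ts <- cfg$t_sd_ms / 1000
    dRT <- cfg$ari_shortening_ms / 1000

    samples <- matrix(0, cfg$n_electrodes, nb * spb)
    truth <- vector("list", cfg$n_electrodes)
    for (e in seq_len(cfg$n_electrodes)) {
      isch_e <- e %in% cfg$ischemic_mask
      norm_beat <- egm_beat_template_(tt, at[e], rt[e], cfg$qrs_amp_mv, qs,
                                      cfg$t_amp_mv, ts, cfg$t_polarity[e], 0)
      row <- rep(norm_beat, nb)
      if (isch_e && any(isch_beat)) {
        isch_tpl <- egm_beat_template_(tt, at[e], rt[e] - dRT, cfg$qrs_amp_mv,
                                       qs, cfg$t_amp_mv, ts,
                                       cfg$t_polarity[e], cfg$st_shift_mv)
        for (b in which(isch_beat))
          row[((b - 1) * spb + 1):(b * spb)] <- isch_tpl
      }
      samples[e, ] <- row
      ie <- isch_e & isch_beat
      truth[[e]] <- tibble::tibble(
        electrode_id = e, beat_index = seq_len(nb), onset_s = onsets,
        at_s = onsets + at[e],
        rt_s = onsets + ifelse(ie, rt[e] - dRT, rt[e]),
        st_mv = ifelse(ie, cfg$st_shift_mv, 0),
        ischemic = ie
      )
    }
    if (cfg$noise_sd_mv > 0)
      samples <- samples + matrix(rnorm(length(samples), 0, cfg$noise_sd_mv),
                                  nrow(samples))
    truth <- dplyr::bind_rows(truth)
    truth$ari_ms <- (truth$rt_s - truth$at_s) * 1000
    list(egm = egm_set(samples, fs, seq_len(cfg$n_electrodes), onsets),
         truth = truth)
  })
}
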