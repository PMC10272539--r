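#' Antidromic identification of IML neurons
#'
#' Preganglionic sympathetic neurons of the intermediolateral column (IML)
#' project into the paravertebral chain, so chain stimulation activates
#' them antidromically at a near-fixed latency. For each stimulation pulse
#' the first spike in the half-open window `(pulse, pulse + window_ms]` is
#' taken as the candidate response, each spike answering at most one pulse
#' (one-to-one). A unit is classified IML when the follow fraction exceeds
#' `min_frac` and the response latency is consistent (SD at most
#' `max_latency_sd_ms`).
#'
#' @param t numeric spike times (s) of one unit.
#' @param pulses stimulation pulse times (s); at least 10 required.
#' @param window_ms response window after each pulse (default 50).
#' @param min_frac follow-fraction threshold; classification requires a
#'   strictly greater fraction (default 0.6, i.e. "more than 60%").
#' @param max_latency_sd_ms latency-consistency threshold (default 5).
#' @return One-row tibble: `n_pulses`, `n_responses`, `follow_fraction`,
#'   `latency_mean_ms`, `latency_sd_ms`, `is_iml`.
#' @export
identify_iml <- function(t, pulses, window_ms = 50, min_frac = 0.6,
                         max_latency_sd_ms = 5) {
  if (length(pulses) == 0) stop("no stimulation pulses supplied", call. = FALSE)
  if (length(pulses) < 10)
    stop("antidromic identification needs at least 10 pulses", call. = FALSE)
  pulses <- sort(pulses)
  t <- sort(t)
  w <- window_ms / 1000
  lat <- rep(NA_real_, length(pulses))
  j <- 1L; n <- length(t)
  for (i in seq_along(pulses)) {
    while (j <= n && t[j] <= pulses[i]) j <- j + 1L
    if (j <= n && t[j] <= pulses[i] + w) {
      lat[i] <- (t[j] - pulses[i]) * 1000
      j <- j + 1L # one-to-one: the spike answers this pulse only
    }
  }
  nr <- sum(!is.na(lat))
  frac <- nr / length(pulses)
  lm <- if (nr > 0) mean(lat, na.rm = TRUE) else NA_real_
  ls <- if (nr >= 2) sd(lat, na.rm = TRUE) else NA_real_
  tibble::tibble(
    n_pulses = length(pulses), n_responses = nr, follow_fraction = frac,
    latency_mean_ms = lm, latency_sd_ms = ls,
    is_iml = frac > min_frac && !is.na(ls) && ls <= max_latency_sd_ms
  )
}

#' Antidromic screen over a population
#'
#' Runs [identify_iml()] for every neuron and assigns region labels: units
#' passing the antidromic criteria are IML, all others dorsal horn (DH).
#'
#' @param spikes spike tibble.
#' @param pulses stimulation pulse times (s).
#' @inheritParams identify_iml
#' @return Tibble with `neuron_id`, the [identify_iml()] columns and
#'   `region` (`"IML"` or `"DH"`).
#' @export
classify_regions <- function(spikes, pulses, window_ms = 50, min_frac = 0.6,
                             max_latency_sd_ms = 5) {
  assert_spike_table_(spikes)
  by_n <- split(spikes$t, spikes$neuron_id)
  out <- purrr::map_dfr(names(by_n), function(id) {
    dplyr::mutate(identify_iml(by_n[[id]], pulses, window_ms, min_frac,
                               max_latency_sd_ms),
                  neuron_id = id, .before = 1)
  })
  dplyr::mutate(out, region = ifelse(.data$is_iml, "IML", "DH"))
}

#' Mechanosensitive / nociceptive / multimodal labelling
#'
#' A neuron is mechanosensitive when its rate increases significantly
#' during either epicardial touch epoch, nociceptive when it increases
#' during the bradykinin or capsaicin application, and multimodal when
#' both. Each stimulus epoch is compared against the equally long window
#' immediately preceding it (matched-duration rate-change test). Missing
#' stimulus epochs leave the corresponding label `NA`.
#'
#' @param spikes spike tibble.
#' @param timeline a [protocol_timeline()] with stimulus epochs among
#'   `touch_rv`, `touch_lv`, `bradykinin`, `capsaicin`.
#' @param alpha significance level.
#' @param method test variant, see [skellam_test()].
#' @return Tibble `neuron_id`, `mechano`, `nociceptive`, `multimodal`.
#' @export
classify_modalities <- function(spikes, timeline, alpha = 0.05,
                                method = "exact") {
  assert_spike_table_(spikes)
  stim_sets <- list(mechano = c("touch_rv", "touch_lv"),
                    nociceptive = c("bradykinin", "capsaicin"))
  by_n <- split(spikes$t, spikes$neuron_id)
  test_epoch <- function(t, name) {
    win <- epoch_window(timeline, name)
    len <- win[2] - win[1]
    ref <- c(win[1] - len, win[1])
    st <- skellam_test(count_in_epoch(t, ref), len,
                       count_in_epoch(t, win), len,
                       alpha = alpha, method = method)
    st$direction == "increase"
  }
  purrr::map_dfr(names(by_n), function(id) {
    t <- by_n[[id]]
    lab <- lapply(stim_sets, function(eps) {
      eps <- eps[vapply(eps, has_epoch, logical(1), timeline = timeline)]
      if (length(eps) == 0) return(NA)
      any(vapply(eps, function(e) test_epoch(t, e), logical(1)))
    })
    tibble::tibble(neuron_id = id, mechano = lab$mechano,
                   nociceptive = lab$nociceptive,
                   multimodal = lab$mechano & lab$nociceptive)
  })
}
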