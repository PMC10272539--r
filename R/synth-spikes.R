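#' Synthetic spike population configuration
#'
#' Describes a population of spinal units as inhomogeneous Poisson
#' processes with piecewise-constant rates tied to the protocol epochs:
#' each neuron fires at `baseline_rate_hz` times an epoch gain. The gain is
#' `ischemia_gain` during `lad_pre`, `post_scs_gain` during `lad_post`, 1
#' elsewhere; `epoch_gains` can override the gain of any epoch (e.g. touch
#' or bradykinin responses). Antidromically driven units additionally fire
#' at each stimulation pulse plus a near-fixed latency, with probability
#' `follow_prob` per pulse; synchronized pairs receive common injected
#' events placed in both trains with a uniform lag. A 1 ms refractory merge
#' is applied last.
#'
#' @param n_neurons population size.
#' @param baseline_rate_hz baseline firing rate(s), recycled per neuron.
#' @param ischemia_gain multiplicative rate factor during `lad_pre`
#'   (1 = ischemia-insensitive), recycled.
#' @param post_scs_gain rate factor during `lad_post`, emulating the
#'   suppressed response after spinal cord stimulation, recycled.
#' @param antidromic `NULL`, or a data frame with columns `neuron`
#'   (integer index), `latency_ms`, `latency_jitter_ms` (uniform half-width),
#'   `follow_prob`.
#' @param sync_pairs `NULL`, or a data frame with columns `a`, `b` (integer
#'   indices), `injection_rate_hz`, `max_lag_ms`.
#' @param epoch_gains `NULL`, or a data frame with columns `neuron`,
#'   `epoch`, `gain` overriding the gain of specific epochs.
#' @param n_electrodes electrodes available; neurons are assigned
#'   round-robin.
#' @param duration_s record length; `NULL` uses the timeline extent.
#' @param seed RNG seed; identical seeds give identical spike times.
#' @return A list of class `synth_spike_config`.
#' @export
synth_spike_config <- function(n_neurons = 250, baseline_rate_hz = 2,
                               ischemia_gain = 1, post_scs_gain = 1,
                               antidromic = NULL, sync_pairs = NULL,
                               epoch_gains = NULL, n_electrodes = 64,
                               duration_s = NULL, seed = NULL) {
  baseline_rate_hz <- rep_len(baseline_rate_hz, n_neurons)
  ischemia_gain <- rep_len(ischemia_gain, n_neurons)
  post_scs_gain <- rep_len(post_scs_gain, n_neurons)
  if (any(baseline_rate_hz < 0) || any(ischemia_gain < 0) || any(post_scs_gain < 0))
    stop("rates and gains must be >= 0", call. = FALSE)
  if (!is.null(antidromic)) {
    antidromic <- tibble::as_tibble(antidromic)
    stopifnot(all(c("neuron", "latency_ms", "latency_jitter_ms",
                    "follow_prob") %in% names(antidromic)))
    if (any(antidromic$follow_prob < 0 | antidromic$follow_prob > 1))
      stop("follow_prob must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(sync_pairs)) {
    sync_pairs <- tibble::as_tibble(sync_pairs)
    stopifnot(all(c("a", "b", "injection_rate_hz", "max_lag_ms")
                  %in% names(sync_pairs)))
  }
  if (!is.null(epoch_gains)) {
    epoch_gains <- tibble::as_tibble(epoch_gains)
    stopifnot(all(c("neuron", "epoch", "gain") %in% names(epoch_gains)))
  }
  structure(
    list(n_neurons = n_neurons, baseline_rate_hz = baseline_rate_hz,
         ischemia_gain = ischemia_gain, post_scs_gain = post_scs_gain,
         antidromic = antidromic, sync_pairs = sync_pairs,
         epoch_gains = epoch_gains, n_electrodes = n_electrodes,
         duration_s = duration_s, seed = seed),
    class = "synth_spike_config"
  )
}

# piecewise-constant rate segments for one neuron:
# returns list(breaks, rates) with breaks covering [0, duration]
rate_segments_ <- function(i, cfg, timeline, duration) {
  ep <- timeline$epochs
  gain_of <- function(name) {
    g <- NA_real_
    if (!is.null(cfg$epoch_gains)) {
      hit <- cfg$epoch_gains$neuron == i & cfg$epoch_gains$epoch == name
      if (any(hit)) g <- cfg$epoch_gains$gain[which(hit)[1]]
    }
    if (!is.na(g)) return(g)
    switch(name, lad_pre = cfg$ischemia_gain[i],
           lad_post = cfg$post_scs_gain[i], 1)
  }
  # stimulus epochs take precedence over the analysis epoch they sit in
  stim_names <- c("touch_rv", "touch_lv", "bradykinin", "capsaicin")
  breaks <- sort(unique(c(0, duration,
                          pmin(ep$start, duration), pmin(ep$end, duration))))
  mids <- head(breaks, -1) + diff(breaks) / 2
  rates <- vapply(mids, function(m) {
    inside <- which(ep$start <= m & m < ep$end)
    if (length(inside) == 0) return(cfg$baseline_rate_hz[i])
    nm <- ep$epoch[inside]
    pick <- if (any(nm %in% stim_names)) nm[nm %in% stim_names][1] else nm[1]
    cfg$baseline_rate_hz[i] * gain_of(pick)
  }, 0)
  list(breaks = breaks, rates = rates)
}

#' Generate a synthetic spike population with ground truth
#'
#' Spike trains are drawn by thinning: a homogeneous Poisson process at the
#' neuron's maximal rate is simulated over the record and each event is
#' kept with probability `rate(t) / rate_max`. Antidromic and injected
#' common-drive events are then superimposed and a 1 ms refractory merge is
#' applied (earliest spike of any closer pair is kept).
#'
#' @param cfg a [synth_spike_config()].
#' @param timeline a [protocol_timeline()]; antidromic units respond to
#'   `timeline$stim_pulses$t2`.
#' @return A list with
#'   `spikes`: tibble (`neuron_id`, `electrode_id`, `t`);
#'   `truth`: per-neuron tibble with the generating parameters and the
#'     labels `is_sensitive` (ischemia gain > 1) and `is_iml` (antidromic);
#'   `sync_truth`: the injected pair table (with neuron ids);
#'   `adjacency`: a 4-neighbour grid adjacency over the electrodes used.
#' @examples
#' tl <- default_study_timeline()
#' cfg <- synth_spike_config(n_neurons = 4, baseline_rate_hz = 2, seed = 1)
#' pop <- gen_spike_population(cfg, tl)
#' head(pop$spikes)
#' @export
gen_spike_population <- function(cfg, timeline) {
  stopifnot(inherits(cfg, "synth_spike_config"),
            inherits(timeline, "protocol_timeline"))
  duration <- if (is.null(cfg$duration_s)) max(timeline$epochs$end) else cfg$duration_s
  nd <- max(3L, nchar(as.character(cfg$n_neurons)))
  ids <- sprintf(paste0("n%0", nd, "d"), seq_len(cfg$n_neurons))
  electrode <- ((seq_len(cfg$n_neurons) - 1L) %% cfg$n_electrodes) + 1L
  pulses <- if (length(timeline$stim_pulses) > 0) timeline$stim_pulses[[1]] else numeric(0)

  with_seed_(cfg$seed, {
    trains <- vector("list", cfg$n_neurons)
    for (i in seq_len(cfg$n_neurons)) {
      seg <- rate_segments_(i, cfg, timeline, duration)
      rmax <- max(seg$rates)
      sp <- numeric(0)
      if (rmax > 0) {
        n <- rpois(1, rmax * duration)
        tt <- sort(runif(n, 0, duration))
        r_at <- seg$rates[findInterval(tt, seg$breaks, rightmost.closed = TRUE)]
        sp <- tt[runif(n) < r_at / rmax]
      }
      if (!is.null(cfg$antidromic)) {
        row <- which(cfg$antidromic$neuron == i)
        if (length(row) == 1 && length(pulses) > 0) {
          a <- cfg$antidromic[row, ]
          hit <- runif(length(pulses)) < a$follow_prob
          jit <- runif(sum(hit), -a$latency_jitter_ms, a$latency_jitter_ms)
          sp <- c(sp, pulses[hit] + a$latency_ms / 1000 + jit / 1000)
        }
      }
      trains[[i]] <- sp
    }
    if (!is.null(cfg$sync_pairs)) {
      for (k in seq_len(nrow(cfg$sync_pairs))) {
        p <- cfg$sync_pairs[k, ]
        ne <- rpois(1, p$injection_rate_hz * duration)
        ev <- runif(ne, 0, duration)
        lag <- runif(ne, -p$max_lag_ms, p$max_lag_ms) / 1000
        trains[[p$a]] <- c(trains[[p$a]], ev)
        trains[[p$b]] <- c(trains[[p$b]], pmin(pmax(ev + lag, 0), duration))
      }
    }
    spikes <- purrr::map_dfr(seq_len(cfg$n_neurons), function(i) {
      sp <- sort(trains[[i]])
      if (length(sp) > 1) sp <- sp[c(TRUE, diff(sp) >= 0.001)]
      tibble::tibble(neuron_id = ids[i], electrode_id = electrode[i], t = sp)
    })
    is_iml <- seq_len(cfg$n_neurons) %in%
      (if (is.null(cfg$antidromic)) integer(0) else cfg$antidromic$neuron)
    truth <- tibble::tibble(
      neuron_id = ids, electrode_id = electrode,
      baseline_rate_hz = cfg$baseline_rate_hz,
      ischemia_gain = cfg$ischemia_gain, post_scs_gain = cfg$post_scs_gain,
      is_sensitive = cfg$ischemia_gain > 1, is_iml = is_iml
    )
    sync_truth <- if (is.null(cfg$sync_pairs)) NULL else
      dplyr::mutate(cfg$sync_pairs, a_id = ids[.data$a], b_id = ids[.data$b])
    ncol_grid <- ceiling(cfg$n_electrodes / 8)
    adjacency <- grid_adjacency(min(8, cfg$n_electrodes), ncol_grid)
    adjacency <- adjacency[as.integer(names(adjacency)) <= cfg$n_electrodes]
    adjacency <- lapply(adjacency, function(v) v[v <= cfg$n_electrodes])
    list(spikes = spikes, truth = truth, sync_truth = sync_truth,
         adjacency = adjacency)
  })
}
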