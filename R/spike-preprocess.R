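#' Cross-electrode artifact rejection
#'
#' A single neuron cannot appear on several electrodes of a high-impedance
#' penetrating array, so near-simultaneous events on more than two adjacent
#' electrodes are electrical artifacts. Spikes are clustered by time (gaps
#' of at most `tol_ms` chain into one cluster); within a cluster, any set
#' of electrodes that is connected in the adjacency map and spans more than
#' two electrodes has all of its cluster spikes removed. Events on two or
#' fewer electrodes, or on non-adjacent electrodes, are always kept. The
#' operation is idempotent.
#'
#' @param spikes spike tibble (`neuron_id`, `electrode_id`, `t`).
#' @param adjacency named list mapping electrode id to adjacent ids (see
#'   [read_adjacency()], [grid_adjacency()]).
#' @param tol_ms coincidence tolerance in ms (default 0.5).
#' @return The cleaned tibble, with the removed rows attached as attribute
#'   `"artifact_log"` (retrieve with [artifact_log()]).
#' @export
remove_artifacts <- function(spikes, adjacency, tol_ms = 0.5) {
  assert_spike_table_(spikes)
  ids <- sort(unique(c(as.integer(names(adjacency)),
                       unlist(adjacency, use.names = FALSE),
                       spikes$electrode_id)))
  adj <- adjacency_matrix_(adjacency, ids)
  ord <- order(spikes$t)
  s <- spikes[ord, ]
  flag <- .artifact_flags_cpp(s$t, match(s$electrode_id, ids) - 1L, adj,
                              tol_ms / 1000)
  removed <- s[flag, ]
  kept <- dplyr::arrange(s[!flag, ], .data$neuron_id, .data$t)
  attr(kept, "artifact_log") <- removed
  kept
}

#' @rdname remove_artifacts
#' @param x a tibble returned by `remove_artifacts()`.
#' @export
artifact_log <- function(x) {
  attr(x, "artifact_log")
}

#' Count spikes in a half-open window
#'
#' @param t numeric spike times, or a spike tibble (counted per neuron).
#' @param epoch `c(start, end)`; spikes with `start <= t < end` count.
#' @return An integer, or a tibble (`neuron_id`, `n`) for tabular input.
#' @export
count_in_epoch <- function(t, epoch) {
  if (is.data.frame(t)) {
    assert_spike_table_(t, "t")
    keep <- in_window_(t$t, epoch)
    return(dplyr::count(t[keep, ], .data$neuron_id, name = "n"))
  }
  sum(in_window_(t, epoch))
}

#' Binned firing-rate series
#'
#' Counts per contiguous bin divided by the bin width. The final bin is
#' truncated at `duration`, and its rate uses the truncated width.
#'
#' @param spikes spike tibble, or a numeric vector of times for one train.
#' @param bin_s bin width in seconds (a 30 s window is typical for epoch
#'   overview plots).
#' @param duration record length; defaults to the last spike time.
#' @return Tibble with `neuron_id` (if tabular input), `bin_start`,
#'   `bin_end`, `rate_hz`.
#' @export
rate_series <- function(spikes, bin_s = 30, duration = NULL) {
  stopifnot(bin_s > 0)
  one <- function(t, id = NULL) {
    dur <- if (is.null(duration)) max(t, 0) else duration
    edges <- unique(c(seq(0, dur, by = bin_s), dur))
    if (length(edges) < 2) edges <- c(0, max(dur, bin_s))
    n <- length(edges) - 1
    counts <- vapply(seq_len(n), function(i)
      sum(t >= edges[i] & t < edges[i + 1]), 0L)
    # the record endpoint belongs to the last bin
    counts[n] <- counts[n] + sum(t == edges[n + 1])
    out <- tibble::tibble(bin_start = edges[-length(edges)],
                          bin_end = edges[-1],
                          rate_hz = counts / diff(edges))
    if (!is.null(id)) out <- dplyr::mutate(out, neuron_id = id, .before = 1)
    out
  }
  if (is.data.frame(spikes)) {
    assert_spike_table_(spikes)
    if (is.null(duration)) duration <- max(spikes$t, 0)
    by_neuron <- split(spikes$t, spikes$neuron_id)
    return(purrr::map2_dfr(by_neuron, names(by_neuron), one))
  }
  one(spikes)
}
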