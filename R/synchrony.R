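#' Coincidence count between two spike trains
#'
#' Greedy one-to-one matching in time order: each reference spike is
#' matched to the nearest still-unmatched target spike within
#' `window_ms` (|lag| <= window), so a burst in one train cannot inflate
#' the count through a single spike of the other. Deterministic; ties go
#' to the earlier target spike.
#'
#' @param ref,target numeric spike times in seconds.
#' @param window_ms coincidence half-width in ms (default 40: two spikes
#'   coincide when they fire within 40 ms of one another).
#' @param epoch optional `c(start, end)`; both trains are restricted to the
#'   half-open window first.
#' @return Integer count of matched pairs.
#' @export
count_coincidences <- function(ref, target, window_ms = 40, epoch = NULL) {
  if (!is.null(epoch)) {
    ref <- ref[in_window_(ref, epoch)]
    target <- target[in_window_(target, epoch)]
  }
  if (length(ref) == 0 || length(target) == 0) return(0L)
  .count_coincidences_cpp(sort(ref), sort(target), window_ms / 1000)
}

#' Jitter-surrogate null for coincidence counts
#'
#' Estimates how many coincidences two trains would show by chance, given
#' their slow rate structure: in each surrogate every target spike is
#' displaced by an independent uniform draw on `[-J, +J]` (J well above the
#' coincidence window, well below rate-modulation timescales) and the
#' coincidences are recounted. Jitter destroys fine-timescale synchrony
#' while preserving slow co-modulation, so the surrogate distribution is
#' the appropriate chance reference for high-firing pairs.
#'
#' @inheritParams count_coincidences
#' @param jitter_half_width_ms uniform jitter half-width J (default 200 ms).
#' @param n_surrogates number of surrogates (>= 100; default 1000).
#' @param seed RNG seed for the surrogate draws.
#' @return A list: `null_mean`, `null_sd`, `counts` (the surrogate
#'   distribution).
#' @export
jitter_null <- function(ref, target, window_ms = 40,
                        jitter_half_width_ms = 200, n_surrogates = 1000,
                        seed = NULL, epoch = NULL) {
  if (n_surrogates < 100)
    stop("at least 100 surrogates are required", call. = FALSE)
  if (is.null(epoch))
    epoch <- range(c(ref, target, 0))
  else {
    ref <- ref[in_window_(ref, epoch)]
    target <- target[in_window_(target, epoch)]
  }
  if (diff(epoch) < 2 * jitter_half_width_ms / 1000)
    warning("epoch shorter than twice the jitter half-width")
  ref <- sort(ref)
  J <- jitter_half_width_ms / 1000
  w <- window_ms / 1000
  with_seed_(seed, {
    counts <- vapply(seq_len(n_surrogates), function(s) {
      if (length(target) == 0) return(0L)
      tj <- target + runif(length(target), -J, J)
      tj <- pmin(pmax(tj, epoch[1]), epoch[2])
      .count_coincidences_cpp(ref, sort(tj), w)
    }, 0L)
    list(null_mean = mean(counts), null_sd = sd(counts), counts = counts)
  })
}

#' Jitter-normalized synchrony index for one pair
#'
#' The synchrony index contrasts the observed coincidence count with the
#' jitter-surrogate chance level:
#' `si = (c_obs - null_mean) / (c_obs + null_mean)` (0 when both terms are
#' 0), so two independent high-rate neurons score near 0 while genuinely
#' locked pairs approach 1. Significance is the one-sided surrogate rank,
#' `p = (1 + #\{surrogate >= c_obs\}) / (1 + n_surrogates)`.
#'
#' @inheritParams jitter_null
#' @param alpha significance level.
#' @return An object of class `synchrony_result` (also a one-row tibble):
#'   `c_obs`, `null_mean`, `null_sd`, `si`, `p_value`, `significant`,
#'   `defined` (`FALSE` when either train has no spike in the epoch, in
#'   which case the pair is excluded from aggregates).
#' @export
synchrony_index <- function(ref, target, window_ms = 40,
                            jitter_half_width_ms = 200, n_surrogates = 1000,
                            alpha = 0.05, seed = NULL, epoch = NULL) {
  if (!is.null(epoch)) {
    ref <- ref[in_window_(ref, epoch)]
    target <- target[in_window_(target, epoch)]
  }
  if (length(ref) == 0 || length(target) == 0) {
    out <- tibble::tibble(c_obs = NA_integer_, null_mean = NA_real_,
                          null_sd = NA_real_, si = NA_real_,
                          p_value = NA_real_, significant = NA,
                          defined = FALSE)
    class(out) <- c("synchrony_result", class(out))
    return(out)
  }
  ep <- if (is.null(epoch)) range(c(ref, target, 0)) else epoch
  c_obs <- count_coincidences(ref, target, window_ms)
  nl <- jitter_null(ref, target, window_ms, jitter_half_width_ms,
                    n_surrogates, seed = seed, epoch = ep)
  si <- if (c_obs + nl$null_mean == 0) 0 else
    (c_obs - nl$null_mean) / (c_obs + nl$null_mean)
  p <- (1 + sum(nl$counts >= c_obs)) / (1 + length(nl$counts))
  out <- tibble::tibble(c_obs = c_obs, null_mean = nl$null_mean,
                        null_sd = nl$null_sd, si = si, p_value = p,
                        significant = p < alpha, defined = TRUE)
  class(out) <- c("synchrony_result", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.synchrony_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Pairwise synchrony over a labelled population
#'
#' Evaluates the synchrony index for every DH-DH and DH-IML pair, per
#' epoch. Surrogate seeds are derived deterministically from `seed`, the
#' pair and the epoch, so the full table is reproducible.
#'
#' @param spikes spike tibble.
#' @param regions tibble with `neuron_id` and `region` (`"DH"`/`"IML"`),
#'   e.g. from [classify_regions()].
#' @param timeline a [protocol_timeline()].
#' @param epochs epoch names to analyse.
#' @param neurons optional subset of neuron ids to consider.
#' @inheritParams synchrony_index
#' @return Tibble with one row per pair and epoch: `ref_id`, `target_id`,
#'   `category` (`"DH-DH"`/`"DH-IML"`), `epoch` and the
#'   [synchrony_index()] columns.
#' @export
pairwise_synchrony <- function(spikes, regions, timeline,
                               epochs = c("lad_pre", "lad_post"),
                               neurons = NULL, window_ms = 40,
                               jitter_half_width_ms = 200,
                               n_surrogates = 1000, alpha = 0.05, seed = 1) {
  assert_spike_table_(spikes)
  if (!is.null(neurons))
    regions <- regions[regions$neuron_id %in% neurons, ]
  dh <- regions$neuron_id[regions$region == "DH"]
  iml <- regions$neuron_id[regions$region == "IML"]
  pairs <- dplyr::bind_rows(
    if (length(dh) >= 2)
      tibble::tibble(ref_id = t(utils::combn(dh, 2))[, 1],
                     target_id = t(utils::combn(dh, 2))[, 2],
                     category = "DH-DH"),
    if (length(dh) >= 1 && length(iml) >= 1)
      tidyr::expand_grid(ref_id = dh, target_id = iml) |>
        dplyr::mutate(category = "DH-IML")
  )
  if (is.null(pairs) || nrow(pairs) == 0)
    return(tibble::tibble())
  by_n <- split(spikes$t, spikes$neuron_id)
  out <- vector("list", nrow(pairs) * length(epochs))
  k <- 0L
  for (ep_name in epochs) {
    ep <- epoch_window(timeline, ep_name)
    for (i in seq_len(nrow(pairs))) {
      k <- k + 1L
      pair_seed <- (seed * 10007L + i * 101L +
                      match(ep_name, epochs)) %% .Machine$integer.max
      res <- synchrony_index(by_n[[pairs$ref_id[i]]],
                             by_n[[pairs$target_id[i]]],
                             window_ms, jitter_half_width_ms, n_surrogates,
                             alpha, seed = pair_seed, epoch = ep)
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(ref_id = pairs$ref_id[i],
                       target_id = pairs$target_id[i],
                       category = pairs$category[i], epoch = ep_name),
        tibble::as_tibble(unclass(res)))
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate synchrony per category and epoch
#'
#' Reports, per pair category and epoch, the number of significant pairs
#' and the summed synchrony index over significant pairs (undefined pairs
#' excluded).
#'
#' @param pairs a [pairwise_synchrony()] table.
#' @return Tibble `category`, `epoch`, `n_pairs`, `n_significant`,
#'   `si_sum_significant`.
#' @export
synchrony_summary <- function(pairs) {
  pairs |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$category, .data$epoch) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_significant = sum(.data$significant),
      si_sum_significant = sum(.data$si[.data$significant]),
      .groups = "drop"
    )
}
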