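#' Read a sorted spike-event table
#'
#' Spike tables are delimited text with columns `neuron_id`,
#' `electrode_id`, `t_seconds` — one row per sorted action potential.
#' Times are seconds from recording start. Rows are returned sorted by
#' neuron then time regardless of input order; duplicate timestamps within
#' a neuron are collapsed with a warning (a sorted unit cannot fire twice
#' at the same instant).
#'
#' @param path path to a CSV file.
#' @return A tibble with columns `neuron_id` (character),
#'   `electrode_id` (integer), `t` (numeric seconds).
#' @seealso [read_adjacency()] for the electrode adjacency map.
#' @export
read_spike_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "electrode_id", "t_seconds")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("spike table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(df$t_seconds) | df$t_seconds < 0 |
                 is.na(df$neuron_id) | is.na(df$electrode_id))
  if (length(bad) > 0) {
    warning("dropping ", length(bad), " malformed row(s) at line(s): ",
            paste(head(bad + 1L, 10), collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  out <- tibble::tibble(
    neuron_id = as.character(df$neuron_id),
    electrode_id = as.integer(df$electrode_id),
    t = as.numeric(df$t_seconds)
  )
  out <- dplyr::arrange(out, .data$neuron_id, .data$t)
  dup <- duplicated(out[c("neuron_id", "t")])
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate timestamp(s) within neurons")
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' @rdname read_spike_table
#' @param spikes spike tibble (`neuron_id`, `electrode_id`, `t`).
#' @export
write_spike_table <- function(spikes, path) {
  assert_spike_table_(spikes)
  df <- data.frame(
    neuron_id = spikes$neuron_id,
    electrode_id = spikes$electrode_id,
    t_seconds = sprintf("%.6f", spikes$t)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an electrode adjacency map
#'
#' Adjacency is supplied as data (probe layouts vary): a JSON object
#' mapping each electrode id to the array of its adjacent electrode ids.
#' The map is symmetrised on read.
#'
#' @param path JSON file path.
#' @return A named list of integer vectors.
#' @export
read_adjacency <- function(path) {
  adj <- jsonlite::read_json(path, simplifyVector = TRUE)
  adj <- lapply(adj, as.integer)
  ids <- sort(unique(c(as.integer(names(adj)), unlist(adj))))
  m <- adjacency_matrix_(adj, ids)
  out <- lapply(seq_along(ids), function(i) ids[m[i, ]])
  setNames(out, ids)
}

#' @rdname read_adjacency
#' @param adjacency named list of integer vectors.
#' @export
write_adjacency <- function(adjacency, path) {
  jsonlite::write_json(adjacency, path, auto_unbox = FALSE)
  invisible(path)
}

#' Rectangular grid adjacency
#'
#' 4-neighbour adjacency for a probe whose electrodes are laid out on an
#' `nrow` x `ncol` grid, numbered column-major starting at `first_id`.
#'
#' @param nrow,ncol grid dimensions.
#' @param first_id id of the first electrode.
#' @return Named list of integer vectors, as [read_adjacency()].
#' @export
grid_adjacency <- function(nrow = 8, ncol = 8, first_id = 1L) {
  ids <- matrix(seq_len(nrow * ncol) + first_id - 1L, nrow, ncol)
  out <- list()
  for (id in sort(as.vector(ids))) {
    pos <- which(ids == id, arr.ind = TRUE)
    r <- pos[1]; c <- pos[2]
    nb <- integer(0)
    if (r > 1) nb <- c(nb, ids[r - 1, c])
    if (r < nrow) nb <- c(nb, ids[r + 1, c])
    if (c > 1) nb <- c(nb, ids[r, c - 1])
    if (c < ncol) nb <- c(nb, ids[r, c + 1])
    out[[as.character(id)]] <- sort(nb)
  }
  out
}
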