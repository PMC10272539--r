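# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# Restores the caller's RNG state afterwards so library code never
# perturbs user-level randomness.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# half-open [start, end) membership
in_window_ <- function(t, window) {
  t >= window[1] & t < window[2]
}

assert_spike_table_ <- function(x, arg = "spikes") {
  if (!is.data.frame(x)) stop("`", arg, "` must be a data frame", call. = FALSE)
  need <- c("neuron_id", "electrode_id", "t")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("`", arg, "` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$t < 0)) stop("spike times must be >= 0", call. = FALSE)
  invisible(x)
}

# adjacency: named list electrode_id -> integer vector of neighbours.
# Returns a symmetric logical matrix indexed by position in `ids`.
adjacency_matrix_ <- function(adjacency, ids) {
  n <- length(ids)
  m <- matrix(FALSE, n, n)
  for (nm in names(adjacency)) {
    i <- match(as.integer(nm), ids)
    if (is.na(i)) next
    j <- match(as.integer(adjacency[[nm]]), ids)
    j <- j[!is.na(j)]
    m[i, j] <- TRUE
    m[j, i] <- TRUE
  }
  diag(m) <- FALSE
  m
}
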