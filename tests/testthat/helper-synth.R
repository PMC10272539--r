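# Shared fixtures: tiny timelines and pure-R reference implementations used
# as independent oracles for the compiled kernels.

tiny_timeline <- function() {
  protocol_timeline(list(baseline_pre = c(0, 60), lad_pre = c(60, 240)),
                    stim_pulses = list(t2 = seq(5, by = 1, length.out = 50)))
}

# Reference greedy one-to-one matcher (readable, O(n^2)); the compiled
# counter must agree with it exactly.
count_coincidences_ref <- function(ref, target, window) {
  ref <- sort(ref); target <- sort(target)
  used <- rep(FALSE, length(target))
  n <- 0L
  for (t in ref) {
    d <- abs(target - t)
    d[used | d > window] <- Inf
    if (any(is.finite(d))) {
      used[which.min(d)] <- TRUE
      n <- n + 1L
    }
  }
  n
}

# Reference artifact rule: cluster spikes by <= tol gaps, remove spikes on
# connected adjacent electrode sets of size > 2.
remove_artifacts_ref <- function(spikes, adjacency, tol_ms = 0.5) {
  s <- spikes[order(spikes$t), ]
  tol <- tol_ms / 1000
  cl <- cumsum(c(1, diff(s$t) > tol))
  drop <- logical(nrow(s))
  for (g in split(seq_len(nrow(s)), cl)) {
    el <- unique(s$electrode_id[g])
    if (length(el) < 3) next
    # connected components in the adjacency subgraph
    comp <- seq_along(el)
    repeat {
      changed <- FALSE
      for (i in seq_along(el)) for (j in seq_along(el)) {
        if (comp[i] != comp[j] &&
            el[j] %in% adjacency[[as.character(el[i])]]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    sizes <- table(comp)
    bad_el <- el[comp %in% as.integer(names(sizes)[sizes >= 3])]
    drop[g] <- s$electrode_id[g] %in% bad_el
  }
  s[!drop, ]
}
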