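#' Protocol timeline
#'
#' A protocol timeline names the analysis epochs of an ischemia /
#' spinal-cord-stimulation experiment and carries stimulus pulse trains.
#' Epoch intervals are half-open `[start, end)` in seconds from recording
#' start, so a spike at an epoch boundary is counted exactly once.
#'
#' Analysis epochs (`baseline_pre`, `lad_pre`, `rep_pre`, `scs`,
#' `baseline_post`, `lad_post`, `rep_post`) may not overlap one another;
#' stimulus epochs (`touch_rv`, `touch_lv`, `bradykinin`, `capsaicin`) may
#' sit inside a baseline epoch.
#'
#' @param epochs data frame with columns `epoch`, `start`, `end` (seconds),
#'   or a named list of `c(start, end)` pairs.
#' @param stim_pulses named list of numeric vectors of pulse times in
#'   seconds (e.g. `t2` for paravertebral chain stimulation).
#' @return An object of class `protocol_timeline`: a list with elements
#'   `epochs` (tibble) and `stim_pulses`.
#' @examples
#' tl <- protocol_timeline(list(baseline_pre = c(0, 60), lad_pre = c(60, 240)))
#' epoch_window(tl, "lad_pre")
#' @export
protocol_timeline <- function(epochs, stim_pulses = list()) {
  if (!is.data.frame(epochs)) {
    epochs <- tibble::tibble(
      epoch = names(epochs),
      start = unname(vapply(epochs, function(x) as.numeric(x[1]), 0)),
      end = unname(vapply(epochs, function(x) as.numeric(x[2]), 0))
    )
  }
  epochs <- tibble::as_tibble(epochs[c("epoch", "start", "end")])
  if (any(epochs$end <= epochs$start))
    stop("every epoch must have end > start", call. = FALSE)
  if (anyDuplicated(epochs$epoch))
    stop("duplicated epoch names", call. = FALSE)
  stim_names <- c("touch_rv", "touch_lv", "bradykinin", "capsaicin")
  main <- epochs[!epochs$epoch %in% stim_names, , drop = FALSE]
  if (nrow(main) > 1) {
    m <- main[order(main$start), ]
    if (any(m$end[-nrow(m)] > m$start[-1] + 1e-12))
      stop("analysis epochs may not overlap", call. = FALSE)
  }
  lad <- epochs[grepl("^lad", epochs$epoch), , drop = FALSE]
  if (nrow(lad) > 0 && any(lad$end - lad$start < 10))
    warning("LAD epoch shorter than 10 s; the protocol uses 3 min occlusions")
  stim_pulses <- lapply(stim_pulses, function(p) sort(as.numeric(p)))
  structure(list(epochs = epochs, stim_pulses = stim_pulses),
            class = "protocol_timeline")
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat("<protocol_timeline>", nrow(x$epochs), "epochs,",
      length(x$stim_pulses), "pulse train(s)\n")
  print(x$epochs, ...)
  invisible(x)
}

#' Look up an epoch window
#'
#' @param timeline a [protocol_timeline()].
#' @param epoch epoch name.
#' @return `c(start, end)` in seconds.
#' @export
epoch_window <- function(timeline, epoch) {
  i <- match(epoch, timeline$epochs$epoch)
  if (is.na(i)) stop("epoch not in timeline: ", epoch, call. = FALSE)
  unname(c(timeline$epochs$start[i], timeline$epochs$end[i]))
}

#' @rdname epoch_window
#' @export
has_epoch <- function(timeline, epoch) {
  epoch %in% timeline$epochs$epoch
}

#' Read / write a protocol timeline as JSON
#'
#' The JSON document holds an `epochs` object mapping epoch names to
#' `[start, end]` pairs and an optional `stim_pulses` object mapping pulse
#' train names to arrays of pulse times, all in seconds.
#'
#' @param path file path.
#' @return `read_timeline()` returns a [protocol_timeline()];
#'   `write_timeline()` returns `path` invisibly.
#' @export
read_timeline <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$epochs)) stop("timeline JSON must contain 'epochs'", call. = FALSE)
  pulses <- doc$stim_pulses
  if (is.null(pulses)) pulses <- list()
  protocol_timeline(as.list(doc$epochs), pulses)
}

#' @rdname read_timeline
#' @param timeline a [protocol_timeline()].
#' @export
write_timeline <- function(timeline, path) {
  ep <- setNames(
    lapply(seq_len(nrow(timeline$epochs)),
           function(i) c(timeline$epochs$start[i], timeline$epochs$end[i])),
    timeline$epochs$epoch
  )
  jsonlite::write_json(list(epochs = ep, stim_pulses = timeline$stim_pulses),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Default study timeline
#'
#' The reference protocol: a baseline containing the antidromic
#' identification pulse train (60 pulses at 1 Hz) and the epicardial
#' touch / bradykinin / capsaicin stimulus epochs, a 3 min coronary (LAD)
#' occlusion with 3 min reperfusion, a spinal cord stimulation epoch, a
#' 1 min post-SCS baseline, and a second 3 min occlusion plus reperfusion.
#' Total duration 2700 s; the SCS epoch itself is never analysed and is
#' shortened relative to the 30 min used in vivo.
#'
#' @return A [protocol_timeline()].
#' @export
default_study_timeline <- function() {
  protocol_timeline(
    list(
      baseline_pre = c(0, 540),
      lad_pre = c(540, 720),
      rep_pre = c(720, 900),
      scs = c(900, 2280),
      baseline_post = c(2280, 2340),
      lad_post = c(2340, 2520),
      rep_post = c(2520, 2700),
      touch_rv = c(150, 165),
      touch_lv = c(195, 210),
      bradykinin = c(270, 330),
      capsaicin = c(390, 450)
    ),
    stim_pulses = list(t2 = seq(60, by = 1, length.out = 60))
  )
}
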