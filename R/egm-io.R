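#' Multichannel unipolar electrogram container
#'
#' @param samples numeric matrix, one row per electrode, in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param electrode_ids integer ids, one per matrix row.
#' @param beat_marks optional beat-onset times in seconds.
#' @return An object of class `egm_set`.
#' @export
egm_set <- function(samples, fs, electrode_ids = seq_len(nrow(samples)),
                    beat_marks = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (nrow(samples) != length(electrode_ids))
    stop("row count of `samples` must equal length of `electrode_ids`",
         call. = FALSE)
  structure(
    list(samples = unname(samples), fs = as.numeric(fs),
         electrode_ids = as.integer(electrode_ids),
         beat_marks = if (is.null(beat_marks)) NULL else sort(as.numeric(beat_marks))),
    class = "egm_set"
  )
}

#' @export
print.egm_set <- function(x, ...) {
  cat("<egm_set>", nrow(x$samples), "electrodes x", ncol(x$samples),
      "samples @", x$fs, "Hz (",
      round(ncol(x$samples) / x$fs, 3), "s ),",
      length(x$beat_marks), "beat marks\n")
  invisible(x)
}

#' Read / write electrograms as annotated CSV
#'
#' The text representation is: a first line `fs=<Hz>`, an optional second
#' line `beat_marks=<t1;t2;...>` (seconds), then a CSV body whose first
#' column is `electrode_id` and remaining columns are samples in mV.
#'
#' @param path file path.
#' @return `read_electrograms()` returns an [egm_set()].
#' @export
read_electrograms <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !grepl("^fs=", lines[1]))
    stop("electrogram file must start with a 'fs=<Hz>' header line", call. = FALSE)
  fs <- as.numeric(sub("^fs=", "", lines[1]))
  if (is.na(fs) || fs <= 0) stop("invalid fs in header", call. = FALSE)
  body_start <- 2L
  beat_marks <- NULL
  if (grepl("^beat_marks=", lines[2])) {
    bm <- sub("^beat_marks=", "", lines[2])
    if (nzchar(bm)) beat_marks <- as.numeric(strsplit(bm, ";")[[1]])
    body_start <- 3L
  }
  df <- read.csv(text = paste(lines[body_start:length(lines)], collapse = "\n"),
                 header = TRUE)
  if (names(df)[1] != "electrode_id")
    stop("first CSV column must be 'electrode_id'", call. = FALSE)
  egm_set(as.matrix(df[, -1, drop = FALSE]), fs = fs,
          electrode_ids = df$electrode_id, beat_marks = beat_marks)
}

#' @rdname read_electrograms
#' @param egm an [egm_set()].
#' @export
write_electrograms <- function(egm, path) {
  stopifnot(inherits(egm, "egm_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", egm$fs), con)
  if (!is.null(egm$beat_marks))
    writeLines(paste0("beat_marks=",
                      paste(sprintf("%.6f", egm$beat_marks), collapse = ";")), con)
  df <- data.frame(electrode_id = egm$electrode_ids,
                   matrix(sprintf("%.6f", egm$samples), nrow = nrow(egm$samples)))
  names(df) <- c("electrode_id", paste0("s", seq_len(ncol(egm$samples))))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
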