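#' Per-nucleotide stop-count track
#'
#' Holds, for one channel (chemically treated or solvent control) of one
#' transcript, the number of reverse-transcription drop-off events observed
#' at each nucleotide and the number of read fragments covering it.
#'
#' @param ref A [transcript_ref()].
#' @param stops Integer vector, length `ref$length`, non-negative.
#' @param coverage Integer vector, length `ref$length`, non-negative.
#' @param channel `"treated"` or `"control"`.
#'
#' @return Object of class `stop_count_track`.
#' @export
stop_count_track <- function(ref, stops, coverage,
                             channel = c("treated", "control")) {
  stopifnot(inherits(ref, "transcript_ref"))
  channel <- match.arg(channel)
  stops <- as.integer(round(stops))
  coverage <- as.integer(round(coverage))
  if (length(stops) != ref$length || length(coverage) != ref$length) {
    stop("stops/coverage length must equal transcript length (",
         ref$length, ")")
  }
  if (anyNA(stops) || anyNA(coverage) || any(stops < 0L) || any(coverage < 0L)) {
    stop("stops and coverage must be non-negative integers")
  }
  structure(list(transcript = ref, stops = stops, coverage = coverage,
                 channel = channel),
            class = "stop_count_track")
}

#' Treated/control channel pair
#'
#' The unit of two-channel Poisson EM fitting: aligned stop-count tracks for
#' the chemically treated and the solvent-control library of one sample.
#'
#' @param treated,control [stop_count_track()] objects on the same transcript.
#' @param sample_name Sample label carried into downstream call sets.
#' @return Object of class `channel_pair`.
#' @export
channel_pair <- function(treated, control, sample_name = "sample") {
  stopifnot(inherits(treated, "stop_count_track"),
            inherits(control, "stop_count_track"))
  if (treated$transcript$name != control$transcript$name ||
      treated$transcript$length != control$transcript$length) {
    stop("treated and control tracks must reference the same transcript")
  }
  structure(list(treated = treated, control = control,
                 sample_name = sample_name),
            class = "channel_pair")
}

#' @export
print.stop_count_track <- function(x, ...) {
  cat(sprintf("stop_count_track: %s channel on %s (%d nt), %d stops, median coverage %g\n",
              x$channel, x$transcript$name, x$transcript$length,
              sum(x$stops), stats::median(x$coverage)))
  invisible(x)
}

#' @export
print.channel_pair <- function(x, ...) {
  cat(sprintf("channel_pair '%s' on %s (%d nt)\n", x$sample_name,
              x$treated$transcript$name, x$treated$transcript$length))
  invisible(x)
}

# Skip provenance/comment lines and read a tab-delimited table with header.
read_tsv_commented <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load a pre-computed stop/coverage count table
#'
#' Reads a tab-delimited table with header columns `position` (1-based),
#' `stops` and `coverage` into a dense track; positions absent from the
#' table are zero-filled.
#'
#' @param path TSV file. Lines starting with `#` are ignored.
#' @param ref A [transcript_ref()] giving the coordinate frame.
#' @param channel Channel label for the resulting track.
#' @return A [stop_count_track()].
#' @export
load_count_table <- function(path, ref, channel = c("treated", "control")) {
  channel <- match.arg(channel)
  stopifnot(inherits(ref, "transcript_ref"))
  tab <- read_tsv_commented(path)
  need <- c("position", "stops", "coverage")
  if (!all(need %in% names(tab))) {
    stop("count table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  pos <- as.integer(tab$position)
  if (anyNA(pos) || any(pos < 1L) || any(pos > ref$length)) {
    stop("count table positions out of range [1, ", ref$length, "]")
  }
  if (anyDuplicated(pos)) stop("duplicate positions in count table '", path, "'")
  if (any(tab$stops < 0) || any(tab$coverage < 0)) {
    stop("negative counts in count table '", path, "'")
  }
  stops <- integer(ref$length)
  coverage <- integer(ref$length)
  stops[pos] <- as.integer(tab$stops)
  coverage[pos] <- as.integer(tab$coverage)
  stop_count_track(ref, stops, coverage, channel)
}

#' Write a stop-count track as a TSV count table
#'
#' Inverse of [load_count_table()]: all positions are written, so a
#' write/read round trip preserves counts exactly.
#'
#' @param track A [stop_count_track()].
#' @param path Output file.
#' @param provenance Optional named character vector written as `# key: value`
#'   header comment lines.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(track, path, provenance = NULL) {
  stopifnot(inherits(track, "stop_count_track"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(transcript = track$transcript$name,
              length = track$transcript$length,
              channel = track$channel, provenance)
  writeLines(sprintf("# %s: %s", names(header), header), con)
  tab <- data.frame(position = seq_len(track$transcript$length),
                    stops = track$stops, coverage = track$coverage)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
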