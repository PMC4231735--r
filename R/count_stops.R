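#' Count reverse-transcription drop-off events from paired-end alignments
#'
#' Converts properly paired alignments of randomly primed cDNA fragments
#' against a single transcript into a per-nucleotide stop-count and coverage
#' track. The RT drop-off event of a fragment is assigned to
#' `p = pos1 + stop_offset` where `pos1` is the 1-based 5'-most aligned
#' reference position of read 1 (the cDNA 3' end under the adopted library
#' orientation). The default `stop_offset = -1` records the stop one
#' nucleotide 3' of the chemical adduct, where reverse transcriptase
#' terminates; `0` reproduces the read-start dialect. A fragment contributes
#' coverage at every position from its stop through its priming-site end
#' (1-based, closed).
#'
#' Only primary, properly paired, non-duplicate read-1 alignments on the
#' plus strand with mapping quality at least `min_mapq` are used; antisense
#' fragments are discarded and tallied in the returned attributes.
#'
#' @param alignments Path to a BAM file, or to a SAM file (converted on the
#'   fly with [Rsamtools::asBam()]).
#' @param ref A [transcript_ref()] the reads were aligned to; records on
#'   other reference names are ignored (and tallied).
#' @param channel Channel label for the resulting track.
#' @param min_mapq Minimum mapping quality (default 10).
#' @param stop_offset Offset added to the read-1 5' position to obtain the
#'   drop-off position (default -1).
#' @param exclusion_window_3p Stops falling within this many nucleotides of
#'   the transcript 3' end are suppressed from the stop track (they cannot
#'   be distinguished from random-priming artifacts) but still contribute
#'   coverage; default 0 (no exclusion).
#'
#' @return A [stop_count_track()] with attributes `n_fragments` (used),
#'   `n_antisense`, `n_other_ref`, `n_low_mapq`, `n_stop_out_of_range`, and
#'   `n_flagged_3p`.
#' @export
count_stops <- function(alignments, ref, channel = c("treated", "control"),
                        min_mapq = 10L, stop_offset = -1L,
                        exclusion_window_3p = 0L) {
  channel <- match.arg(channel)
  stopifnot(inherits(ref, "transcript_ref"))
  if (exclusion_window_3p < 0L) stop("exclusion_window_3p must be >= 0")
  if (min_mapq < 0L) stop("min_mapq must be >= 0")
  bam <- as_bam_path(alignments)

  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "strand", "pos", "mapq", "isize"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]

  n_total <- length(rec$pos)
  if (n_total == 0L) {
    # degenerate but valid: no usable pairs at all
    has_pairs <- local({
      p2 <- Rsamtools::ScanBamParam(what = "pos")
      length(Rsamtools::scanBam(bam, param = p2)[[1L]]$pos) > 0L
    })
    if (has_pairs) {
      stop("alignment file '", alignments,
           "' contains reads but no properly paired read-1 records; ",
           "paired-end input is required")
    }
  }

  on_ref <- !is.na(rec$rname) & as.character(rec$rname) == ref$name
  n_other_ref <- sum(!on_ref)
  sense <- rec$strand == "+" & rec$isize > 0L
  n_antisense <- sum(on_ref & !sense)
  mq_ok <- is.na(rec$mapq) | rec$mapq >= min_mapq
  n_low_mapq <- sum(on_ref & sense & !mq_ok)
  keep <- on_ref & sense & mq_ok

  pos1 <- rec$pos[keep]
  tlen <- rec$isize[keep]
  L <- ref$length
  p_stop <- pos1 + as.integer(stop_offset)
  frag_end <- pmin(pos1 + tlen - 1L, L)

  in_range <- p_stop >= 1L & p_stop <= L
  n_stop_oor <- sum(!in_range)
  near_3p <- in_range & p_stop > L - as.integer(exclusion_window_3p)
  n_flagged <- sum(near_3p)

  stops <- tabulate(p_stop[in_range & !near_3p], nbins = L)

  cov_start <- pmax(p_stop, 1L)
  inc <- tabulate(cov_start, nbins = L)
  dec <- tabulate(pmin(frag_end + 1L, L + 1L), nbins = L + 1L)
  coverage <- cumsum(inc - dec[seq_len(L)])

  track <- stop_count_track(ref, stops, coverage, channel)
  attr(track, "n_fragments") <- length(pos1)
  attr(track, "n_antisense") <- n_antisense
  attr(track, "n_other_ref") <- n_other_ref
  attr(track, "n_low_mapq") <- n_low_mapq
  attr(track, "n_stop_out_of_range") <- n_stop_oor
  attr(track, "n_flagged_3p") <- n_flagged
  track
}

# Accept either BAM or plain-text SAM; SAM is converted to a temporary
# sorted+indexed BAM.
as_bam_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}
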