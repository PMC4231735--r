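#' Transcript reference
#'
#' A minimal container for a single-transcript reference: the unit of all
#' per-nucleotide analysis in this package. Coordinates are 1-based and
#' closed throughout.
#'
#' @param name Transcript identifier.
#' @param sequence Nucleotide sequence (A, C, G, T/U, N; case-insensitive).
#'   U is converted to T internally; the original alphabet (RNA vs DNA) is
#'   remembered and restored by [ref_sequence()].
#'
#' @return An object of class `transcript_ref` with fields `name`,
#'   `sequence` (uppercase DNA alphabet), `length`, and `is_rna`.
#' @export
transcript_ref <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("empty sequence for transcript '", name, "'")
  }
  if (grepl("[^ACGTUN]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGTUN]", "", sequence), "")[[1L]])
    stop("sequence for '", name, "' contains characters outside A,C,G,T/U,N: ",
         paste(bad, collapse = ", "))
  }
  is_rna <- grepl("U", sequence, fixed = TRUE)
  structure(
    list(name = name,
         sequence = chartr("U", "T", sequence),
         length = nchar(sequence),
         is_rna = is_rna),
    class = "transcript_ref"
  )
}

#' Load a transcript reference from a FASTA file
#'
#' @param fasta Path to a FASTA file with one or more records.
#' @param transcript Record name to select. May be omitted when the file
#'   holds exactly one record. Matching is on the first whitespace-delimited
#'   token of the FASTA header.
#'
#' @return A [transcript_ref()].
#' @export
load_reference <- function(fasta, transcript = NULL) {
  seqs <- tryCatch(Biostrings::readBStringSet(fasta),
                   error = function(e) stop("malformed FASTA '", fasta, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA '", fasta, "' contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.null(transcript)) {
    if (length(seqs) > 1L) {
      stop("FASTA has ", length(seqs),
           " records; specify `transcript` to select one")
    }
    idx <- 1L
  } else {
    idx <- match(transcript, ids)
    if (is.na(idx)) {
      stop("record '", transcript, "' not found in FASTA (records: ",
           paste(utils::head(ids, 10L), collapse = ", "), ")")
    }
  }
  transcript_ref(ids[idx], as.character(seqs[[idx]]))
}

#' Per-position bases of a transcript reference
#'
#' @param ref A [transcript_ref()].
#' @param rna Report in the reference's input alphabet (`TRUE`, default) or
#'   force DNA (`FALSE`).
#' @return Character vector of length `ref$length`.
#' @export
ref_bases <- function(ref, rna = TRUE) {
  stopifnot(inherits(ref, "transcript_ref"))
  b <- strsplit(ref$sequence, "")[[1L]]
  if (rna && ref$is_rna) b <- chartr("T", "U", b)
  b
}

#' @export
ref_sequence <- function(ref) {
  stopifnot(inherits(ref, "transcript_ref"))
  if (ref$is_rna) chartr("T", "U", ref$sequence) else ref$sequence
}

#' @export
print.transcript_ref <- function(x, ...) {
  cat("transcript_ref:", x$name, sprintf("(%d nt, %s)\n", x$length,
      if (x$is_rna) "RNA" else "DNA"))
  invisible(x)
}

#' Write a transcript reference as FASTA
#'
#' @param ref A [transcript_ref()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "transcript_ref"))
  set <- Biostrings::BStringSet(ref$sequence)
  names(set) <- ref$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
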