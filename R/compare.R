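#' Region annotation on a transcript
#'
#' Named intervals (e.g. rRNA helices) in 1-based closed transcript
#' coordinates, used to aggregate per-position comparisons.
#'
#' @param name Character vector of unique region names.
#' @param start,end Integer vectors, `1 <= start <= end`.
#' @return A `region_annotation` data frame.
#' @export
region_annotation <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(name) != length(start) || length(start) != length(end)) {
    stop("name, start and end must have equal length")
  }
  if (anyDuplicated(name)) stop("region names must be unique")
  if (any(start < 1L) || any(end < start)) {
    stop("regions require 1 <= start <= end")
  }
  structure(data.frame(name = as.character(name), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_annotation", "data.frame"))
}

#' Read region annotation from BED or native TSV
#'
#' BED input (detected by the `.bed` extension) is 0-based half-open and is
#' converted to the internal 1-based closed convention via
#' [rtracklayer::import()]. Native TSV input has header columns `name`,
#' `start`, `end`, already 1-based closed.
#'
#' @param path Annotation file.
#' @return A [region_annotation()].
#' @export
read_regions <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else paste0("region", seq_along(gr))
    region_annotation(nm, BiocGenerics::start(gr), BiocGenerics::end(gr))
  } else {
    tab <- read_tsv_commented(path)
    if (!all(c("name", "start", "end") %in% names(tab))) {
      stop("region TSV needs columns name, start, end")
    }
    region_annotation(tab$name, tab$start, tab$end)
  }
}

#' Summarize a modification call set
#'
#' @param calls A [call_modified()] or [read_call_table()] call set.
#' @param ref A [transcript_ref()] supplying the base at each position.
#' @return Object of class `sample_summary`: `sample_name`, `n_called`,
#'   `n_defined`, `calls_by_base` (named integer vector over the bases
#'   actually called), `frac_ac` (fraction of calls on A or C; `NA` when
#'   nothing is called).
#' @export
summarize_calls <- function(calls, ref) {
  stopifnot(inherits(calls, "modification_call_set"),
            inherits(ref, "transcript_ref"))
  if (length(calls$called) != ref$length) {
    stop("call set length (", length(calls$called),
         ") does not match transcript length (", ref$length, ")")
  }
  bases <- ref_bases(ref)
  called_bases <- bases[calls$called]
  by_base <- if (length(called_bases)) table(called_bases) else table(character(0))
  by_base <- stats::setNames(as.integer(by_base), names(by_base))
  n_called <- sum(calls$called)
  frac_ac <- if (n_called > 0) sum(called_bases %in% c("A", "C")) / n_called
             else NA_real_
  structure(list(sample_name = calls$sample_name, n_called = n_called,
                 n_defined = sum(calls$defined), calls_by_base = by_base,
                 frac_ac = frac_ac),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary '%s': %d called of %d defined positions\n",
              x$sample_name, x$n_called, x$n_defined))
  if (length(x$calls_by_base)) {
    cat("  calls by base:",
        paste(sprintf("%s=%d", names(x$calls_by_base), x$calls_by_base),
              collapse = ", "),
        sprintf("(A+C fraction %.3f)\n", x$frac_ac))
  }
  invisible(x)
}

#' Compare modification calls between two samples
#'
#' Assigns every position a status: `both` (called in both samples),
#' `a_only`, `b_only`, `neither` (defined in both, called in neither), or
#' `undefined` (insufficient data in at least one sample). When a region
#' annotation is given, per-region status counts are tabulated, optionally
#' with a Fisher exact test contrasting the two samples' called/uncalled
#' counts within each region (diagnostic only; the per-position calls are
#' the primary comparison).
#'
#' @param a,b [call_modified()] call sets on the same transcript.
#' @param regions Optional [region_annotation()].
#' @param fisher Add a per-region two-proportion Fisher exact p-value
#'   (default `FALSE`).
#' @return Object of class `call_comparison`: `status` (factor per
#'   position), `positions` (data frame), and `regions` (data frame of
#'   per-region counts, or `NULL`).
#' @export
compare_calls <- function(a, b, regions = NULL, fisher = FALSE) {
  stopifnot(inherits(a, "modification_call_set"),
            inherits(b, "modification_call_set"))
  L <- length(a$called)
  if (length(b$called) != L) stop("call sets are on different transcripts")
  ta <- a$transcript_name %||% NA_character_
  tb <- b$transcript_name %||% NA_character_
  if (!is.na(ta) && !is.na(tb) && ta != tb) {
    stop("call sets are on different transcripts: ", ta, " vs ", tb)
  }
  status <- rep("undefined", L)
  joint <- a$defined & b$defined
  status[joint & a$called & b$called] <- "both"
  status[joint & a$called & !b$called] <- "a_only"
  status[joint & !a$called & b$called] <- "b_only"
  status[joint & !a$called & !b$called] <- "neither"
  status <- factor(status,
                   levels = c("both", "a_only", "b_only", "neither", "undefined"))
  positions <- data.frame(position = seq_len(L), status = status,
                          p_modified_a = a$p_modified, p_modified_b = b$p_modified)

  region_tab <- NULL
  if (!is.null(regions)) {
    stopifnot(inherits(regions, "region_annotation"))
    if (any(regions$end > L)) stop("region exceeds transcript length")
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      idx <- regions$start[i]:regions$end[i]
      counts <- table(status[idx])
      row <- data.frame(name = regions$name[i], start = regions$start[i],
                        end = regions$end[i],
                        both = as.integer(counts[["both"]]),
                        a_only = as.integer(counts[["a_only"]]),
                        b_only = as.integer(counts[["b_only"]]),
                        neither = as.integer(counts[["neither"]]),
                        undefined = as.integer(counts[["undefined"]]))
      if (fisher) {
        n_a <- sum(a$called[idx] & joint[idx]); n_b <- sum(b$called[idx] & joint[idx])
        n_def <- sum(joint[idx])
        row$fisher_p <- if (n_def > 0) {
          stats::fisher.test(matrix(c(n_a, n_def - n_a, n_b, n_def - n_b),
                                    nrow = 2L))$p.value
        } else NA_real_
      }
      row
    })
    region_tab <- do.call(rbind, rows)
  }
  structure(list(sample_a = a$sample_name, sample_b = b$sample_name,
                 status = status, positions = positions, regions = region_tab),
            class = "call_comparison")
}

#' @export
print.call_comparison <- function(x, ...) {
  cat(sprintf("call_comparison: %s vs %s\n", x$sample_a, x$sample_b))
  print(table(x$status))
  invisible(x)
}

#' Export a track as a grayscale heat-map intensity table
#'
#' Per-position intensities in [0, 1], max-scaled over the defined
#' positions, written as TSV (position, intensity); undefined positions are
#' written with an empty intensity field. Intended for external block
#' heat-map rendering where each block is one nucleotide.
#'
#' @param x A [dropoff_rates()] track or [reactivity()] profile.
#' @param path Output TSV.
#' @return The intensity vector, invisibly.
#' @export
export_heatmap_track <- function(x, path) {
  vals <- track_values(x)
  if (all(is.na(vals))) stop("empty track: no defined positions")
  mx <- max(vals, na.rm = TRUE)
  intensity <- if (mx > 0) vals / mx else ifelse(is.na(vals), NA_real_, 0)
  out <- data.frame(position = seq_along(vals),
                    intensity = ifelse(is.na(intensity), "",
                                       format(intensity, digits = 10)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(intensity)
}
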