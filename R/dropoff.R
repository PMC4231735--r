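#' Per-nucleotide RT drop-off rates
#'
#' The drop-off rate at a nucleotide is the number of reads stopping there
#' divided by the number of reads covering it. Positions with coverage below
#' `min_coverage` are undefined: their rate is reported as `NA`, never as 0.
#'
#' @param track A [stop_count_track()].
#' @param min_coverage Minimum coverage for a position to be defined
#'   (default 1).
#' @return Object of class `dropoff_rate_track` with fields `transcript`,
#'   `rates` (numeric, `NA` where undefined) and `defined` (logical mask).
#' @export
dropoff_rates <- function(track, min_coverage = 1L) {
  stopifnot(inherits(track, "stop_count_track"))
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  defined <- track$coverage >= min_coverage
  rates <- rep(NA_real_, track$transcript$length)
  rates[defined] <- track$stops[defined] / track$coverage[defined]
  structure(list(transcript = track$transcript, rates = rates,
                 defined = defined, channel = track$channel,
                 min_coverage = as.integer(min_coverage)),
            class = "dropoff_rate_track")
}

#' @export
print.dropoff_rate_track <- function(x, ...) {
  cat(sprintf("dropoff_rate_track on %s: %d/%d positions defined, median rate %.4g\n",
              x$transcript$name, sum(x$defined), x$transcript$length,
              stats::median(x$rates, na.rm = TRUE)))
  invisible(x)
}

#' Pearson correlation of drop-off rates between replicates
#'
#' @param a,b [dropoff_rates()] tracks on the same transcript.
#' @return Pearson correlation over the jointly defined positions.
#' @export
replicate_correlation <- function(a, b) {
  stopifnot(inherits(a, "dropoff_rate_track"), inherits(b, "dropoff_rate_track"))
  if (a$transcript$name != b$transcript$name ||
      a$transcript$length != b$transcript$length) {
    stop("tracks are on different transcripts")
  }
  joint <- a$defined & b$defined
  if (sum(joint) < 3L) {
    stop("need at least 3 jointly defined positions (have ", sum(joint), ")")
  }
  stats::cor(a$rates[joint], b$rates[joint], method = "pearson")
}

# 2-8% normalization factor: discard the top 2% of values, average the next
# 6% (values between the 2nd and 8th percentile from the top). With fewer
# than ~17 values the 2-8% band is empty under floor/ceiling ranking; fall
# back to the single largest remaining value.
norm_factor_two_eight <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("degenerate profile: no defined positions to normalize")
  srt <- sort(values, decreasing = TRUE)
  lo <- floor(0.02 * n) + 1L
  hi <- max(lo, floor(0.08 * n))
  f <- mean(srt[lo:hi])
  if (!is.finite(f) || f <= 0) {
    stop("degenerate profile: 2-8% normalization reference is empty or non-positive")
  }
  f
}

#' Normalized chemical reactivity profile
#'
#' Computes per-nucleotide chemical (SHAPE/DMS) reactivities from a
#' treated/control channel pair. The raw signal at each position is the
#' difference of transformed drop-off rates between channels, floored at 0;
#' the profile is then 2-8% normalized (scaled so that the mean of the
#' values between the 2nd and 8th percentile from the top equals 1) and
#' capped.
#'
#' @param pair A [channel_pair()].
#' @param cap Upper bound applied after normalization (default 3).
#' @param min_coverage Positions with coverage below this in either channel
#'   are undefined and excluded from the normalization reference
#'   (default 20).
#' @param transform `"log"` (default): `ln(rate + pseudocount)` difference;
#'   `"raw"`: plain rate difference.
#' @param pseudocount Added to rates before the log transform (default 1e-4).
#'
#' @return Object of class `reactivity_profile`: fields `transcript`,
#'   `reactivity` (numeric, `NA` undefined), `defined`, `cap`,
#'   `normalization`, plus the transform settings and the normalization
#'   factor as fields `transform`, `pseudocount`, `norm_factor`.
#' @export
reactivity <- function(pair, cap = 3, min_coverage = 20L,
                       transform = c("log", "raw"), pseudocount = 1e-4) {
  stopifnot(inherits(pair, "channel_pair"))
  transform <- match.arg(transform)
  if (cap <= 0) stop("cap must be > 0")
  rt <- dropoff_rates(pair$treated, min_coverage)
  rc <- dropoff_rates(pair$control, min_coverage)
  defined <- rt$defined & rc$defined
  if (!any(defined)) stop("no position has sufficient coverage in both channels")

  f <- switch(transform,
              log = function(r) log(r + pseudocount),
              raw = identity)
  raw <- rep(NA_real_, pair$treated$transcript$length)
  raw[defined] <- pmax(0, f(rt$rates[defined]) - f(rc$rates[defined]))

  nf <- norm_factor_two_eight(raw[defined])
  out <- pmin(raw / nf, cap)
  structure(list(transcript = pair$treated$transcript, reactivity = out,
                 defined = defined, cap = cap,
                 normalization = "two_eight_percent",
                 transform = transform, pseudocount = pseudocount,
                 min_coverage = as.integer(min_coverage), norm_factor = nf),
            class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("reactivity_profile on %s: %d/%d defined, max %.3g (cap %g, %s transform)\n",
              x$transcript$name, sum(x$defined), x$transcript$length,
              max(x$reactivity, na.rm = TRUE), x$cap, x$transform))
  invisible(x)
}

#' Write a combined per-nucleotide reactivity table
#'
#' Columns: position, base, stops_T, cov_T, stops_C, cov_C, rate_T, rate_C,
#' reactivity. Undefined entries are `NA`. Header comment lines record the
#' transform, cap, pseudocount and coverage floor.
#'
#' @param profile A [reactivity()] profile.
#' @param pair The [channel_pair()] it was computed from.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reactivity_table <- function(profile, pair, path) {
  stopifnot(inherits(profile, "reactivity_profile"), inherits(pair, "channel_pair"))
  rt <- dropoff_rates(pair$treated, profile$min_coverage)
  rc <- dropoff_rates(pair$control, profile$min_coverage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s",
                     c("transcript", "sample", "transform", "cap",
                       "pseudocount", "min_coverage", "normalization"),
                     c(profile$transcript$name, pair$sample_name,
                       profile$transform, profile$cap, profile$pseudocount,
                       profile$min_coverage, profile$normalization)), con)
  tab <- data.frame(position = seq_len(profile$transcript$length),
                    base = ref_bases(profile$transcript),
                    stops_T = pair$treated$stops, cov_T = pair$treated$coverage,
                    stops_C = pair$control$stops, cov_C = pair$control$coverage,
                    rate_T = rt$rates, rate_C = rc$rates,
                    reactivity = profile$reactivity)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a reactivity profile in RNAstructure SHAPE format
#'
#' Two columns (position, reactivity), no header; undefined positions are
#' written as -999.
#'
#' @param profile A [reactivity()] profile.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_shape <- function(profile, path) {
  stopifnot(inherits(profile, "reactivity_profile"))
  val <- ifelse(profile$defined, profile$reactivity, -999)
  utils::write.table(
    data.frame(position = seq_len(profile$transcript$length), value = val),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a per-nucleotide track as bedGraph
#'
#' @param x A [dropoff_rates()] track or [reactivity()] profile.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  vals <- track_values(x)
  defined <- !is.na(vals)
  # bedGraph is 0-based half-open
  tab <- data.frame(chrom = x$transcript$name,
                    start = which(defined) - 1L,
                    end = which(defined),
                    value = vals[defined])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", x$transcript$name), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Uniform accessor for per-position values of rate tracks and reactivity
# profiles.
track_values <- function(x) {
  if (inherits(x, "dropoff_rate_track")) return(x$rates)
  if (inherits(x, "reactivity_profile")) return(x$reactivity)
  stop("expected a dropoff_rate_track or reactivity_profile")
}
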