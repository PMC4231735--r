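#' Simulation scenario for probing-channel pairs
#'
#' Describes a synthetic single-transcript probing experiment matching the
#' generative assumptions of the two-channel Poisson mixture: most positions
#' carry a low background drop-off rate in both channels (class U), a small
#' fraction are natural strong stops with a high rate in both channels
#' (class H), and chemically modified positions (class M) have the high rate
#' in the treated channel only. The default modification density of 1/150
#' reflects probing conditions calibrated so that roughly 1 in every 100-300
#' nucleotides carries an adduct.
#'
#' @param length Transcript length L in nt (default 3000).
#' @param mod_density Expected fraction of modified positions (default
#'   1/150). `0` gives a null scenario with no modified positions.
#' @param frac_high_both Fraction of natural strong-stop positions
#'   (default 0.02).
#' @param lambda_low,lambda_high Per-read drop-off rates for the background
#'   and strong-stop regimes (defaults 0.002 and 0.02).
#' @param coverage `"negative_binomial"` (default) or `"fixed"`.
#' @param coverage_mean Mean per-position per-channel coverage (default 500).
#' @param coverage_dispersion Negative-binomial size parameter (default 5);
#'   ignored for fixed coverage.
#' @param mod_bases Optional character vector (e.g. `c("A", "C")` for a
#'   DMS-like probe): the synthetic reference sequence is drawn so that
#'   modified positions carry only these bases.
#' @param seed Integer seed governing every draw (required).
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(length = 3000L, mod_density = 1 / 150,
                                frac_high_both = 0.02,
                                lambda_low = 0.002, lambda_high = 0.02,
                                coverage = c("negative_binomial", "fixed"),
                                coverage_mean = 500, coverage_dispersion = 5,
                                mod_bases = NULL, seed) {
  coverage <- match.arg(coverage)
  if (missing(seed)) stop("a seed is required for reproducibility")
  stopifnot(length >= 10L, mod_density >= 0, mod_density < 1,
            frac_high_both >= 0, frac_high_both <= 1,
            lambda_low > 0, lambda_low < 1, lambda_high > 0, lambda_high < 1,
            coverage_mean > 0, coverage_dispersion > 0)
  if (mod_density > 0 && mod_density * length < 1) {
    stop("infeasible scenario: expected modified count below 1 ",
         "(use mod_density = 0 for a null scenario)")
  }
  structure(list(length = as.integer(length), mod_density = mod_density,
                 frac_high_both = frac_high_both, lambda_low = lambda_low,
                 lambda_high = lambda_high, coverage = coverage,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 mod_bases = mod_bases, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Deterministic sub-seed derivation: keeps all derived seeds < 2^31.
sub_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Simulate a treated/control channel pair with known ground truth
#'
#' Class labels are drawn i.i.d. with `P(M) = round(L * mod_density) / L`
#' and `P(H) = frac_high_both`; per-position per-channel coverage is drawn
#' from the scenario's coverage model (independently across channels); stop
#' counts are Poisson with mean `lambda[class, channel] * coverage`. The
#' output is bit-reproducible from the scenario seed.
#'
#' @param scn A [simulation_scenario()].
#' @param class_labels Optional factor of per-position class labels (levels
#'   U/H/M, length `scn$length`) overriding the random label draw: use the
#'   labels of a previous simulation to emulate a biological replicate of
#'   the same RNA (shared truth, independent library noise).
#' @return Object of class `simulated_truth`: `class_labels` (factor
#'   U/H/M per position), `pair` (a [channel_pair()]), `scenario`.
#' @export
simulate_pair <- function(scn, class_labels = NULL) {
  stopifnot(inherits(scn, "simulation_scenario"))
  L <- scn$length
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  set.seed(sub_seed(scn$seed, 1L))
  if (is.null(class_labels)) {
    p_m <- if (scn$mod_density > 0) round(L * scn$mod_density) / L else 0
    p_h <- scn$frac_high_both
    labels <- sample(c("U", "H", "M"), L, replace = TRUE,
                     prob = c(1 - p_m - p_h, p_h, p_m))
    labels <- factor(labels, levels = c("U", "H", "M"))
  } else {
    stopifnot(length(class_labels) == L,
              all(class_labels %in% c("U", "H", "M")))
    labels <- factor(as.character(class_labels), levels = c("U", "H", "M"))
  }

  set.seed(sub_seed(scn$seed, 2L))
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (!is.null(scn$mod_bases)) {
    m <- labels == "M"
    bases[m] <- sample(scn$mod_bases, sum(m), replace = TRUE)
  }
  ref <- transcript_ref(sprintf("sim_%d", scn$seed),
                        paste(bases, collapse = ""))

  draw_cov <- function(stage) {
    set.seed(sub_seed(scn$seed, stage))
    if (scn$coverage == "fixed") rep(as.integer(round(scn$coverage_mean)), L)
    else stats::rnbinom(L, mu = scn$coverage_mean,
                        size = scn$coverage_dispersion)
  }
  nT <- draw_cov(3L)
  nC <- draw_cov(4L)

  lamT <- ifelse(labels == "U", scn$lambda_low, scn$lambda_high)
  lamC <- ifelse(labels == "H", scn$lambda_high, scn$lambda_low)
  set.seed(sub_seed(scn$seed, 5L))
  dT <- stats::rpois(L, lamT * nT)
  set.seed(sub_seed(scn$seed, 6L))
  dC <- stats::rpois(L, lamC * nC)

  pair <- channel_pair(stop_count_track(ref, dT, nT, "treated"),
                       stop_count_track(ref, dC, nC, "control"),
                       sample_name = sprintf("sim_seed%d", scn$seed))
  structure(list(class_labels = labels, pair = pair, scenario = scn),
            class = "simulated_truth")
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat(sprintf("simulated_truth: L=%d, classes U/H/M = %d/%d/%d (seed %d)\n",
              x$scenario$length, sum(x$class_labels == "U"),
              sum(x$class_labels == "H"), sum(x$class_labels == "M"),
              x$scenario$seed))
  invisible(x)
}

#' Materialize simulated truth as paired-end SAM alignments
#'
#' Writes, for each channel, a minimal valid SAM of properly paired
#' fragments encoding the simulated drop-off events: each stop at position
#' `p` becomes a fragment whose read-1 5' end aligns at `p + 1` (the
#' inverse of the default -1 stop-offset convention of [count_stops()]) and
#' whose mate marks the random-priming site downstream. Fragment-span
#' coverage is determined by the drawn fragment lengths, so the returned
#' object carries an updated truth pair whose coverage vectors are
#' recomputed from the emitted fragments; stop counts are preserved exactly,
#' except at the final transcript position, whose stops cannot be encoded
#' (the read-1 start would fall outside the transcript) and are dropped.
#' Running [count_stops()] on the output reproduces the returned counts
#' bit-exactly.
#'
#' @param truth A [simulate_pair()] result.
#' @param out_prefix Path prefix; writes `<prefix>_treated.sam`,
#'   `<prefix>_control.sam` and `<prefix>_ref.fa`.
#' @param read_length Read length in nt (default 50; clipped at transcript
#'   boundaries).
#' @param fragment_mean,fragment_sd Normal fragment-length model (defaults
#'   150 and 30; truncated below at `read_length`).
#' @return List with `sam` (named character vector of the two SAM paths),
#'   `fasta`, `truth` (updated `simulated_truth`), and `fragments` (the
#'   per-fragment bookkeeping table, one row per emitted pair).
#' @export
simulate_alignments <- function(truth, out_prefix, read_length = 50L,
                                fragment_mean = 150, fragment_sd = 30) {
  stopifnot(inherits(truth, "simulated_truth"))
  scn <- truth$scenario
  ref <- truth$pair$treated$transcript
  L <- ref$length
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  fasta <- paste0(out_prefix, "_ref.fa")
  write_reference(ref, fasta)

  emit_channel <- function(track, channel, stage) {
    set.seed(sub_seed(scn$seed, stage))
    stops <- track$stops
    stops[L] <- 0L   # not encodable: read-1 start would be L + 1
    p <- rep.int(seq_len(L), stops)
    n <- length(p)
    path <- sprintf("%s_%s.sam", out_prefix, channel)
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", ref$name, L)), con)
    if (n == 0L) {
      return(list(path = path,
                  fragments = data.frame(stop = integer(0), start = integer(0),
                                         end = integer(0))))
    }
    fl <- pmax(as.integer(round(stats::rnorm(n, fragment_mean, fragment_sd))),
               as.integer(read_length))
    start <- p + 1L                       # read-1 5' end
    end <- pmin(start + fl - 1L, L)       # priming-site end
    r1_len <- pmin(as.integer(read_length), end - start + 1L)
    r2_len <- pmin(as.integer(read_length), end - start + 1L)
    r2_pos <- end - r2_len + 1L
    tlen <- end - start + 1L
    qname <- sprintf("%s_frag%06d", channel, seq_len(n))
    seq1 <- vapply(r1_len, function(k) strrep("A", k), character(1L))
    seq2 <- vapply(r2_len, function(k) strrep("A", k), character(1L))
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    qname, ref$name, start, r1_len, r2_pos, tlen, seq1)
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    qname, ref$name, r2_pos, r2_len, start, -tlen, seq2)
    writeLines(c(rbind(rec1, rec2)), con)
    list(path = path,
         fragments = data.frame(stop = p, start = start, end = end))
  }

  res_t <- emit_channel(truth$pair$treated, "treated", 7L)
  res_c <- emit_channel(truth$pair$control, "control", 8L)

  frag_counts <- function(frags) {
    stops <- tabulate(frags$stop, nbins = L)
    inc <- tabulate(frags$stop, nbins = L)   # coverage runs stop..end
    dec <- tabulate(pmin(frags$end + 1L, L + 1L), nbins = L + 1L)
    list(stops = stops, coverage = cumsum(inc - dec[seq_len(L)]))
  }
  ct <- frag_counts(res_t$fragments)
  cc <- frag_counts(res_c$fragments)
  new_pair <- channel_pair(
    stop_count_track(ref, ct$stops, ct$coverage, "treated"),
    stop_count_track(ref, cc$stops, cc$coverage, "control"),
    sample_name = truth$pair$sample_name)
  new_truth <- structure(list(class_labels = truth$class_labels,
                              pair = new_pair, scenario = scn),
                         class = "simulated_truth")
  list(sam = c(treated = res_t$path, control = res_c$path),
       fasta = fasta, truth = new_truth,
       fragments = list(treated = res_t$fragments, control = res_c$fragments))
}
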