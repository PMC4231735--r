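# Shared fixtures and independent oracles for the test suite.

random_ref <- function(L, seed = 42L, name = "ref") {
  set.seed(seed)
  transcript_ref(name, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""))
}

# Build a channel pair directly from count vectors.
toy_pair <- function(dT, nT, dC, nC, ref = NULL, sample_name = "toy") {
  L <- length(dT)
  if (is.null(ref)) ref <- random_ref(L)
  channel_pair(stop_count_track(ref, dT, nT, "treated"),
               stop_count_track(ref, dC, nC, "control"),
               sample_name = sample_name)
}

# Independent brute-force oracle for the three-class Poisson mixture:
# exact pmf terms, per position, per class, no log-space tricks.
oracle_pois_pmf <- function(d, m) exp(-m) * m^d / factorial(d)

oracle_enumerate <- function(pair, params) {
  lam <- rbind(U = c(params$lambda_low, params$lambda_low),
               H = c(params$lambda_high, params$lambda_high),
               M = c(params$lambda_high, params$lambda_low))
  dT <- pair$treated$stops; nT <- pair$treated$coverage
  dC <- pair$control$stops; nC <- pair$control$coverage
  defined <- nT > 0 & nC > 0
  L <- length(dT)
  gamma <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("U", "H", "M")))
  ll <- 0
  for (x in which(defined)) {
    terms <- vapply(1:3, function(k) {
      params$weights[k] *
        oracle_pois_pmf(dT[x], lam[k, 1] * nT[x]) *
        oracle_pois_pmf(dC[x], lam[k, 2] * nC[x])
    }, numeric(1))
    ll <- ll + log(sum(terms))
    gamma[x, ] <- terms / sum(terms)
  }
  list(loglik = ll, gamma = gamma, defined = defined)
}

# Rank-based AUROC of a score against a logical label.
auroc <- function(score, label) {
  stopifnot(length(score) == length(label))
  ok <- !is.na(score)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Minimal hand-rolled SAM writer for a set of proper pairs.
write_toy_sam <- function(path, ref_name, ref_len, r1_pos, frag_end,
                          read_len = 50L) {
  n <- length(r1_pos)
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  if (n > 0) {
    r1_len <- pmin(read_len, frag_end - r1_pos + 1L)
    r2_len <- pmin(read_len, frag_end - r1_pos + 1L)
    r2_pos <- frag_end - r2_len + 1L
    tlen <- frag_end - r1_pos + 1L
    q <- sprintf("frag%04d", seq_len(n))
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    q, ref_name, r1_pos, r1_len, r2_pos, tlen,
                    strrep("A", r1_len))
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t*",
                    q, ref_name, r2_pos, r2_len, r1_pos, -tlen,
                    strrep("A", r2_len))
    lines <- c(lines, c(rbind(rec1, rec2)))
  }
  writeLines(lines, path)
  path
}
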