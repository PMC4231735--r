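#' Two-channel Poisson mixture parameters
#'
#' The mixture assumes drop-off counts at a nucleotide are Poisson with mean
#' `lambda * n` where `n` is the read coverage (exposure) and `lambda` is
#' one of two RNA-wide per-read drop-off rates: a background rate
#' `lambda_low` and a strong-stop rate `lambda_high`, taken approximately
#' constant along the RNA. Each nucleotide belongs to one of three classes,
#' defined by the (treated, control) rate pair:
#' \describe{
#'   \item{U}{unmodified: (`lambda_low`, `lambda_low`)}
#'   \item{H}{natural strong stop: (`lambda_high`, `lambda_high`)}
#'   \item{M}{chemically modified: (`lambda_high`, `lambda_low`)}
#' }
#'
#' @param lambda_low,lambda_high Per-read drop-off rates, `0 < lambda_low <=
#'   lambda_high` (if given out of order they are swapped, relabelling the
#'   U and H weights accordingly).
#' @param weights Length-3 non-negative vector `(pi_U, pi_H, pi_M)`; it is
#'   renormalized to sum to 1.
#' @return Object of class `tcpem_params`.
#' @export
tcpem_params <- function(lambda_low, lambda_high,
                         weights = c(0.90, 0.05, 0.05)) {
  stopifnot(length(lambda_low) == 1L, length(lambda_high) == 1L,
            length(weights) == 3L)
  if (!is.finite(lambda_low) || !is.finite(lambda_high) ||
      lambda_low <= 0 || lambda_high <= 0) {
    stop("lambdas must be finite and > 0")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  weights <- weights / sum(weights)
  if (lambda_high < lambda_low) {
    tmp <- lambda_low; lambda_low <- lambda_high; lambda_high <- tmp
    weights <- weights[c(2L, 1L, 3L)]   # relabel U <-> H
  }
  structure(list(lambda_low = lambda_low, lambda_high = lambda_high,
                 weights = stats::setNames(weights, c("U", "H", "M"))),
            class = "tcpem_params")
}

#' @export
print.tcpem_params <- function(x, ...) {
  cat(sprintf("tcpem_params: lambda_low=%.4g lambda_high=%.4g pi=(%.3f, %.3f, %.3f)\n",
              x$lambda_low, x$lambda_high,
              x$weights[1L], x$weights[2L], x$weights[3L]))
  invisible(x)
}

# (treated, control) rate pair per class, rows U, H, M.
class_lambda_matrix <- function(params) {
  with(params, matrix(c(lambda_low,  lambda_low,
                        lambda_high, lambda_high,
                        lambda_high, lambda_low),
                      nrow = 3L, byrow = TRUE,
                      dimnames = list(c("U", "H", "M"), c("T", "C"))))
}

# Positions usable for fitting: nonzero coverage in both channels.
pair_defined <- function(pair) {
  pair$treated$coverage > 0L & pair$control$coverage > 0L
}

# n x 3 matrix of log(pi_k) + log Pois(d_T; lam_kT n_T) + log Pois(d_C; lam_kC n_C)
# over the defined positions, entirely in log space.
log_joint_matrix <- function(pair, params, idx) {
  lam <- class_lambda_matrix(params)
  dT <- pair$treated$stops[idx];  nT <- pair$treated$coverage[idx]
  dC <- pair$control$stops[idx];  nC <- pair$control$coverage[idx]
  out <- matrix(NA_real_, length(dT), 3L, dimnames = list(NULL, c("U", "H", "M")))
  for (k in 1:3) {
    out[, k] <- log(params$weights[k]) +
      stats::dpois(dT, lam[k, "T"] * nT, log = TRUE) +
      stats::dpois(dC, lam[k, "C"] * nC, log = TRUE)
  }
  out
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Mixture log-likelihood of a channel pair
#'
#' @param pair A [channel_pair()].
#' @param params [tcpem_params()].
#' @return Total log-likelihood over positions with nonzero coverage in
#'   both channels.
#' @export
tcpem_loglik <- function(pair, params) {
  stopifnot(inherits(pair, "channel_pair"), inherits(params, "tcpem_params"))
  idx <- which(pair_defined(pair))
  if (length(idx) == 0L) return(0)
  ll <- sum(logsumexp_rows(log_joint_matrix(pair, params, idx)))
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

#' E-step: per-nucleotide class posteriors
#'
#' @param pair A [channel_pair()].
#' @param params [tcpem_params()].
#' @return Object of class `tcpem_posterior`: `gamma` (L x 3 matrix of
#'   posteriors over U/H/M, `NA` rows where undefined) and `defined`
#'   (logical mask; positions with zero coverage in either channel are
#'   excluded, not zero).
#' @export
tcpem_e_step <- function(pair, params) {
  stopifnot(inherits(pair, "channel_pair"), inherits(params, "tcpem_params"))
  L <- pair$treated$transcript$length
  defined <- pair_defined(pair)
  gamma <- matrix(NA_real_, L, 3L, dimnames = list(NULL, c("U", "H", "M")))
  idx <- which(defined)
  if (length(idx) > 0L) {
    lj <- log_joint_matrix(pair, params, idx)
    gamma[idx, ] <- exp(lj - logsumexp_rows(lj))
  }
  structure(list(gamma = gamma, defined = defined),
            class = "tcpem_posterior")
}

#' M-step: closed-form weighted-ratio parameter updates
#'
#' Class weights are posterior means; the background rate pools the U-class
#' counts in both channels with the M-class control channel, the strong-stop
#' rate pools the H-class counts in both channels with the M-class treated
#' channel, each divided by the matching posterior-weighted coverage. The
#' ordering `lambda_high >= lambda_low` is re-imposed by swap-with-relabel
#' if violated.
#'
#' @param pair A [channel_pair()].
#' @param post A [tcpem_e_step()] posterior.
#' @param prev Previous [tcpem_params()], used to carry a rate forward when a
#'   class has vanishing posterior mass (its weight is floored at 1e-12).
#' @param fix_weights Keep the class weights of `prev` instead of updating
#'   them (requires `prev`).
#' @return Updated [tcpem_params()].
#' @export
tcpem_m_step <- function(pair, post, prev = NULL, fix_weights = FALSE) {
  stopifnot(inherits(pair, "channel_pair"), inherits(post, "tcpem_posterior"))
  idx <- which(post$defined)
  if (length(idx) == 0L) stop("no defined positions")
  g <- post$gamma[idx, , drop = FALSE]
  dT <- pair$treated$stops[idx];  nT <- pair$treated$coverage[idx]
  dC <- pair$control$stops[idx];  nC <- pair$control$coverage[idx]

  w <- colMeans(g)
  eps <- 1e-12
  w <- pmax(w, eps)
  w <- w / sum(w)
  if (fix_weights) {
    if (is.null(prev)) stop("fix_weights requires `prev` parameters")
    w <- prev$weights
  }

  num_low  <- sum(g[, "U"] * (dT + dC) + g[, "M"] * dC)
  den_low  <- sum(g[, "U"] * (nT + nC) + g[, "M"] * nC)
  num_high <- sum(g[, "H"] * (dT + dC) + g[, "M"] * dT)
  den_high <- sum(g[, "H"] * (nT + nC) + g[, "M"] * nT)

  floor_rate <- 1e-9
  lambda_low <- if (den_low > 0) max(num_low / den_low, floor_rate)
                else if (!is.null(prev)) prev$lambda_low else floor_rate
  lambda_high <- if (den_high > 0) max(num_high / den_high, floor_rate)
                 else if (!is.null(prev)) prev$lambda_high else lambda_low
  tcpem_params(lambda_low, lambda_high, w)
}

# Deterministic initialization: quantiles of the pooled per-position
# drop-off rates over both channels.
tcpem_auto_init <- function(pair) {
  idx <- which(pair_defined(pair))
  rates <- c(pair$treated$stops[idx] / pair$treated$coverage[idx],
             pair$control$stops[idx] / pair$control$coverage[idx])
  q <- stats::quantile(rates, c(0.25, 0.99), names = FALSE, type = 7)
  tcpem_params(max(q[1L], 1e-6), max(q[2L], 1e-6), c(0.90, 0.05, 0.05))
}

#' Fit the two-channel Poisson mixture by expectation-maximization
#'
#' Alternates [tcpem_e_step()] and [tcpem_m_step()] until the relative
#' change in log-likelihood falls below `tol` or `max_iter` is reached. The
#' fit is deterministic given the initialization; the default automatic
#' initialization (25th/99th percentile of pooled drop-off rates, weights
#' (0.90, 0.05, 0.05)) is itself deterministic. A decreasing log-likelihood
#' beyond a small relative slack aborts with an error (it would indicate an
#' implementation fault, not a data problem).
#'
#' @param pair A [channel_pair()] with at least 10 positions of nonzero
#'   coverage in both channels.
#' @param init `"auto"` or a [tcpem_params()] starting point.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param fix_weights Keep class weights fixed at their initial values.
#' @return Object of class `tcpem_fit`: `params`, `posterior`,
#'   `log_likelihood_trace`, `converged`, `n_iterations`, `sample_name`.
#' @export
tcpem_fit <- function(pair, init = "auto", tol = 1e-8, max_iter = 1000L,
                      fix_weights = FALSE) {
  stopifnot(inherits(pair, "channel_pair"))
  if (tol <= 0) stop("tol must be > 0")
  n_usable <- sum(pair_defined(pair))
  if (n_usable < 10L) {
    stop("need >= 10 positions with nonzero coverage in both channels (have ",
         n_usable, ")")
  }
  params <- if (identical(init, "auto")) tcpem_auto_init(pair)
            else { stopifnot(inherits(init, "tcpem_params")); init }

  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  for (iter in seq_len(max_iter)) {
    post <- tcpem_e_step(pair, params)
    ll <- tcpem_loglik(pair, params)
    if (length(trace) > 0L) {
      prev_ll <- trace[length(trace)]
      if (ll < prev_ll - 1e-8 * abs(prev_ll)) {
        stop(sprintf(
          "EM log-likelihood decreased (%.10g -> %.10g): internal error",
          prev_ll, ll))
      }
      if (abs(ll - prev_ll) < tol * abs(prev_ll)) {
        trace <- c(trace, ll)
        converged <- TRUE
        break
      }
    }
    trace <- c(trace, ll)
    params <- tcpem_m_step(pair, post, prev = params,
                           fix_weights = fix_weights)
  }
  structure(list(params = params, posterior = post,
                 log_likelihood_trace = trace, converged = converged,
                 n_iterations = length(trace),
                 sample_name = pair$sample_name),
            class = "tcpem_fit")
}

#' @export
print.tcpem_fit <- function(x, ...) {
  cat(sprintf("tcpem_fit '%s': %d iterations (%s), loglik %.4f\n",
              x$sample_name, x$n_iterations,
              if (x$converged) "converged" else "max_iter reached",
              x$log_likelihood_trace[length(x$log_likelihood_trace)]))
  print(x$params)
  invisible(x)
}

#' Call modified nucleotides from a fitted mixture
#'
#' A nucleotide is called modified only if its posterior probability of the
#' modified class is strictly greater than `threshold` (default 0.90).
#'
#' @param fit A [tcpem_fit()].
#' @param threshold Posterior threshold in (0, 1); strict inequality.
#' @param statistic `"p_modified"` (default): threshold the M-class
#'   posterior; `"one_minus_p_unmodified"`: threshold `1 - P(U)` instead.
#' @return Object of class `modification_call_set`: `threshold`,
#'   `p_modified`, `called` (logical; `FALSE` cannot be distinguished from
#'   undefined without `defined`), `defined`, `sample_name`.
#' @export
call_modified <- function(fit, threshold = 0.90,
                          statistic = c("p_modified", "one_minus_p_unmodified")) {
  stopifnot(inherits(fit, "tcpem_fit"))
  statistic <- match.arg(statistic)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p_mod <- fit$posterior$gamma[, "M"]
  stat <- switch(statistic,
                 p_modified = p_mod,
                 one_minus_p_unmodified = 1 - fit$posterior$gamma[, "U"])
  called <- !is.na(stat) & stat > threshold
  structure(list(threshold = threshold, statistic = statistic,
                 p_modified = p_mod, called = called,
                 defined = fit$posterior$defined,
                 sample_name = fit$sample_name),
            class = "modification_call_set")
}

#' @export
print.modification_call_set <- function(x, ...) {
  cat(sprintf("modification_call_set '%s': %d called of %d defined (threshold %g on %s)\n",
              x$sample_name, sum(x$called), sum(x$defined), x$threshold,
              x$statistic))
  invisible(x)
}

#' Write per-nucleotide posteriors and calls as TSV
#'
#' Columns: position, base, d_T, n_T, d_C, n_C, p_U, p_H, p_M, called.
#' Header comments record the fitted parameters, threshold, iteration count
#' and convergence status.
#'
#' @param fit A [tcpem_fit()].
#' @param calls A [call_modified()] call set from the same fit.
#' @param pair The fitted [channel_pair()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(fit, calls, pair, path) {
  stopifnot(inherits(fit, "tcpem_fit"), inherits(calls, "modification_call_set"),
            inherits(pair, "channel_pair"))
  con <- file(path, "w")
  on.exit(close(con))
  p <- fit$params
  writeLines(sprintf("# %s: %s",
    c("transcript", "sample", "lambda_low", "lambda_high",
      "pi_U", "pi_H", "pi_M", "threshold", "statistic", "iterations",
      "converged"),
    c(pair$treated$transcript$name, fit$sample_name,
      format(p$lambda_low, digits = 10), format(p$lambda_high, digits = 10),
      format(p$weights[1L], digits = 10), format(p$weights[2L], digits = 10),
      format(p$weights[3L], digits = 10), calls$threshold, calls$statistic,
      fit$n_iterations, fit$converged)), con)
  g <- fit$posterior$gamma
  tab <- data.frame(position = seq_len(nrow(g)),
                    base = ref_bases(pair$treated$transcript),
                    d_T = pair$treated$stops, n_T = pair$treated$coverage,
                    d_C = pair$control$stops, n_C = pair$control$coverage,
                    p_U = g[, "U"], p_H = g[, "H"], p_M = g[, "M"],
                    called = as.integer(calls$called))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a call table written by [write_call_table()]
#'
#' @param path TSV path.
#' @return A `modification_call_set` (threshold and sample name recovered
#'   from the header comments).
#' @export
read_call_table <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ", "", kv)
  }
  tab <- read_tsv_commented(path)
  need <- c("position", "p_M", "called")
  if (!all(need %in% names(tab))) {
    stop("call table '", path, "' lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  structure(list(threshold = as.numeric(meta$threshold %||% 0.90),
                 statistic = meta$statistic %||% "p_modified",
                 p_modified = tab$p_M,
                 called = tab$called > 0L,
                 defined = !is.na(tab$p_M),
                 sample_name = meta$sample %||% basename(path),
                 transcript_name = meta$transcript %||% NA_character_,
                 base = if ("base" %in% names(tab)) tab$base else NULL),
            class = "modification_call_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
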