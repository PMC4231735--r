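test_that("loglik and e_step match brute-force enumeration on toy pairs", {
  params <- tcpem_params(0.003, 0.03, c(0.9, 0.04, 0.06))

  # closed-form zero-count case, single position
  p0 <- toy_pair(0L, 100L, 0L, 80L)
  lam <- c(0.003, 0.03)
  manual <- log(0.9  * exp(-lam[1] * 100) * exp(-lam[1] * 80) +
                0.04 * exp(-lam[2] * 100) * exp(-lam[2] * 80) +
                0.06 * exp(-lam[2] * 100) * exp(-lam[1] * 80))
  expect_equal(tcpem_loglik(p0, params), manual, tolerance = 1e-12)

  # two-position toy pair, exhaustive term-by-term oracle
  p2 <- toy_pair(c(1L, 4L), c(200L, 150L), c(0L, 3L), c(180L, 160L))
  oc <- oracle_enumerate(p2, params)
  expect_equal(tcpem_loglik(p2, params), oc$loglik, tolerance = 1e-10)

  # five-position pair: posteriors against the oracle
  p5 <- toy_pair(c(0L, 2L, 10L, 1L, 6L), c(300L, 250L, 280L, 10L, 200L),
                 c(1L, 0L, 9L, 0L, 0L), c(290L, 260L, 270L, 12L, 210L))
  oc5 <- oracle_enumerate(p5, params)
  post <- tcpem_e_step(p5, params)
  expect_equal(post$gamma, oc5$gamma, tolerance = 1e-10)
  expect_equal(rowSums(post$gamma), rep(1, 5), tolerance = 1e-9)
})

test_that("collapsed classes make the likelihood weight-independent and posteriors equal weights", {
  p <- toy_pair(c(2L, 0L, 5L), c(100L, 120L, 90L), c(1L, 1L, 4L),
                c(110L, 100L, 95L))
  a <- tcpem_params(0.01, 0.01, c(0.8, 0.1, 0.1))
  b <- tcpem_params(0.01, 0.01, c(0.2, 0.3, 0.5))
  expect_equal(tcpem_loglik(p, a), tcpem_loglik(p, b), tolerance = 1e-12)
  post <- tcpem_e_step(p, a)
  for (x in 1:3) expect_equal(unname(post$gamma[x, ]), c(0.8, 0.1, 0.1),
                              tolerance = 1e-12)
})

test_that("a dominating treated-only signal drives the modified posterior to 1", {
  p <- toy_pair(c(80L, rep(1L, 10)), rep(1000L, 11),
                c(2L, rep(1L, 10)), rep(1000L, 11))
  params <- tcpem_params(0.001, 0.05, c(0.9, 0.05, 0.05))
  post <- tcpem_e_step(p, params)
  expect_gt(post$gamma[1, "M"], 0.999)
  # zero-coverage positions are excluded, not NaN
  p$control$coverage[5] <- 0L
  post2 <- tcpem_e_step(p, params)
  expect_false(post2$defined[5])
  expect_true(all(is.na(post2$gamma[5, ])))
})

test_that("m_step reproduces spreadsheet-style weighted-ratio updates", {
  p <- toy_pair(c(3L, 20L, 15L), c(500L, 400L, 450L),
                c(2L, 18L, 1L), c(480L, 420L, 440L))
  g <- rbind(c(0.90, 0.05, 0.05),
             c(0.10, 0.80, 0.10),
             c(0.05, 0.05, 0.90))
  colnames(g) <- c("U", "H", "M")
  post <- structure(list(gamma = g, defined = rep(TRUE, 3)),
                    class = "tcpem_posterior")
  got <- tcpem_m_step(p, post)

  dT <- p$treated$stops; nT <- p$treated$coverage
  dC <- p$control$stops; nC <- p$control$coverage
  lam_low <- sum(g[, 1] * (dT + dC) + g[, 3] * dC) /
             sum(g[, 1] * (nT + nC) + g[, 3] * nC)
  lam_high <- sum(g[, 2] * (dT + dC) + g[, 3] * dT) /
              sum(g[, 2] * (nT + nC) + g[, 3] * nT)
  expect_equal(got$lambda_low, lam_low, tolerance = 1e-12)
  expect_equal(got$lambda_high, lam_high, tolerance = 1e-12)
  expect_equal(unname(got$weights), unname(colMeans(g)), tolerance = 1e-9)
})

test_that("m_step reduces to pooled rates for a single class and respects channel symmetry", {
  p <- toy_pair(c(3L, 5L, 2L), c(500L, 400L, 450L),
                c(4L, 3L, 3L), c(480L, 420L, 440L))
  gU <- matrix(rep(c(1, 0, 0), each = 3), 3, dimnames = list(NULL, c("U", "H", "M")))
  post <- structure(list(gamma = gU, defined = rep(TRUE, 3)),
                    class = "tcpem_posterior")
  prev <- tcpem_params(0.001, 0.05)
  got <- tcpem_m_step(p, post, prev = prev)
  pooled <- sum(p$treated$stops + p$control$stops) /
            sum(p$treated$coverage + p$control$coverage)
  expect_equal(got$lambda_low, pooled, tolerance = 1e-12)
  expect_equal(got$lambda_high, prev$lambda_high)  # vanished class keeps prev

  # channel swap with gamma(M) = 0 everywhere leaves estimates unchanged
  gUH <- matrix(c(0.7, 0.3, 0), 3, 3, byrow = TRUE,
                dimnames = list(NULL, c("U", "H", "M")))
  postUH <- structure(list(gamma = gUH, defined = rep(TRUE, 3)),
                      class = "tcpem_posterior")
  swapped <- channel_pair(
    stop_count_track(p$treated$transcript, p$control$stops,
                     p$control$coverage, "treated"),
    stop_count_track(p$treated$transcript, p$treated$stops,
                     p$treated$coverage, "control"))
  a <- tcpem_m_step(p, postUH)
  b <- tcpem_m_step(swapped, postUH)
  expect_equal(a$lambda_low, b$lambda_low, tolerance = 1e-12)
  expect_equal(a$lambda_high, b$lambda_high, tolerance = 1e-12)
})

test_that("EM fitting recovers simulation parameters and keeps a monotone trace", {
  scn <- simulation_scenario(length = 5000, mod_density = 0.04,
                             frac_high_both = 0.02, lambda_low = 0.002,
                             lambda_high = 0.02, seed = 1)
  truth <- simulate_pair(scn)
  fit <- tcpem_fit(truth$pair)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$lambda_low - 0.002) / 0.002, 0.2)
  expect_lt(abs(fit$params$lambda_high - 0.02) / 0.02, 0.2)
  expect_lt(abs(fit$params$weights["M"] - mean(truth$class_labels == "M")),
            0.02)
  tr <- fit$log_likelihood_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  s <- rowSums(fit$posterior$gamma[fit$posterior$defined, ])
  expect_true(all(abs(s - 1) < 1e-9))
})

test_that("fitting is deterministic and label-swap invariant", {
  truth <- simulate_pair(simulation_scenario(length = 1000, mod_density = 0.02,
                                             seed = 77))
  f1 <- tcpem_fit(truth$pair)
  f2 <- tcpem_fit(truth$pair)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log_likelihood_trace, f2$log_likelihood_trace)

  init <- tcpem_params(0.001, 0.03, c(0.9, 0.05, 0.05))
  init_swapped <- tcpem_params(0.03, 0.001, c(0.05, 0.9, 0.05))
  fa <- tcpem_fit(truth$pair, init = init)
  fb <- tcpem_fit(truth$pair, init = init_swapped)
  expect_equal(fa$params$lambda_low, fb$params$lambda_low, tolerance = 1e-12)
  expect_equal(fa$params$lambda_high, fb$params$lambda_high, tolerance = 1e-12)
  expect_equal(fa$params$weights, fb$params$weights, tolerance = 1e-12)
})

test_that("identical channels yield essentially no modification calls", {
  set.seed(55)
  L <- 2000L
  ref <- random_ref(L)
  cov <- rpois(L, 500)
  st <- rpois(L, 0.003 * cov)
  pair <- channel_pair(stop_count_track(ref, st, cov, "treated"),
                       stop_count_track(ref, st, cov, "control"))
  fit <- tcpem_fit(pair)
  calls <- call_modified(fit, 0.90)
  expect_lte(sum(calls$called), 2L)
  expect_lte(fit$params$weights["M"], 0.05 + 1e-6)
})

test_that("calling uses a strict threshold and is monotone in it", {
  truth <- simulate_pair(simulation_scenario(length = 2000, mod_density = 0.02,
                                             seed = 13))
  fit <- tcpem_fit(truth$pair)

  # exact-threshold posterior is not called (strictly greater than)
  fit_edge <- fit
  fit_edge$posterior$gamma[1, ] <- c(0.05, 0.05, 0.90)
  calls_edge <- call_modified(fit_edge, 0.90)
  expect_false(calls_edge$called[1])

  n_calls <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99),
                    function(t) sum(call_modified(fit, t)$called), numeric(1))
  expect_true(all(diff(n_calls) <= 0))

  fit_zero <- fit
  fit_zero$posterior$gamma[, "M"] <- 0
  expect_equal(sum(call_modified(fit_zero, 0.9)$called), 0L)
  expect_error(call_modified(fit, 1), "in \\(0, 1\\)")

  # alternative statistic: 1 - P(U)
  alt <- call_modified(fit, 0.90, statistic = "one_minus_p_unmodified")
  expect_gte(sum(alt$called), sum(call_modified(fit, 0.90)$called))
})

test_that("fit preconditions are enforced", {
  small <- toy_pair(rep(0L, 5), rep(10L, 5), rep(0L, 5), rep(10L, 5))
  expect_error(tcpem_fit(small), ">= 10 positions")
  ok <- simulate_pair(simulation_scenario(length = 200, mod_density = 0.02,
                                          seed = 2))
  expect_error(tcpem_fit(ok$pair, tol = 0), "tol")
})

test_that("call tables round-trip through write/read", {
  truth <- simulate_pair(simulation_scenario(length = 500, mod_density = 0.02,
                                             seed = 99))
  fit <- tcpem_fit(truth$pair)
  calls <- call_modified(fit, 0.90)
  f <- tempfile(fileext = ".tsv")
  write_call_table(fit, calls, truth$pair, f)
  back <- read_call_table(f)
  expect_equal(back$called, calls$called)
  expect_equal(back$p_modified, unname(calls$p_modified), tolerance = 1e-6)
  expect_equal(back$threshold, 0.90)
  expect_equal(back$sample_name, truth$pair$sample_name)
})
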