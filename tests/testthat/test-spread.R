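test_that("colonization rate follows m * x^(delta/3)", {
  expect_equal(colonization_rate(1e9, 0.05, 2), 5e4)
  expect_equal(colonization_rate(12345, 0.07, 0), 0.07)   # delta 0: rate is m
  for (d in c(0, 0.7, 1.5, 2, 3)) {
    expect_equal(colonization_rate(1, 0.05, d), 0.05)     # x = 1 for every delta
  }
  expect_error(colonization_rate(-1, 0.05, 2), "non-negative")
  expect_error(spread_params(m = 0.05, delta = 3.5, a = 0.2, N0 = 1e6, T = 10),
               "\\[0, 3\\]")
})

test_that("expected colony count matches quadrature and its stated limits", {
  p0 <- spread_params(m = 0.05, delta = 1.8, a = 0.26, N0 = 1e6, T = 0)
  expect_equal(expected_colony_count(p0), 0)

  p3 <- spread_params(m = 0.02, delta = 3, a = 0.3, N0 = 1e5, T = 8)
  expect_equal(expected_colony_count(p3), (0.02 * 1e5 / 0.3) * (exp(0.3 * 8) - 1),
               tolerance = 1e-12)

  p <- spread_params(m = 0.05, delta = 1.8, a = 0.26, N0 = 1e6, T = 14)
  expect_equal(expected_colony_count(p), lambda_quad(p), tolerance = 1e-8)

  set.seed(1)
  for (i in 1:5) {
    pr <- spread_params(m = runif(1, 0.01, 0.2), delta = runif(1, 0.2, 2.8),
                        a = runif(1, 0.05, 0.4), N0 = 10^runif(1, 3, 7),
                        T = runif(1, 2, 20))
    expect_equal(expected_colony_count(pr), lambda_quad(pr), tolerance = 1e-8)
  }
})

test_that("expected DTC total matches quadrature and its stated limits", {
  pm0 <- spread_params(m = 0, delta = 2, a = 0.26, N0 = 1e6, T = 14)
  expect_equal(expected_total_dtc(pm0), 0)

  p3 <- spread_params(m = 0.01, delta = 3, a = 0.2, N0 = 1e4, T = 6,
                      lung_fraction = 0.4)
  expect_equal(expected_total_dtc(p3), 0.4 * 0.01 * 1e4 * 6 * exp(0.2 * 6),
               tolerance = 1e-12)

  set.seed(2)
  for (i in 1:5) {
    pr <- spread_params(m = runif(1, 0.01, 0.2), delta = runif(1, 0.2, 2.8),
                        a = runif(1, 0.05, 0.4), N0 = 10^runif(1, 3, 7),
                        T = runif(1, 2, 20), lung_fraction = runif(1, 0.2, 1))
    expect_equal(expected_total_dtc(pr), dtc_quad(pr), tolerance = 1e-8)
  }
})

test_that("simulator agrees with the Poisson law at delta = 0 and is deterministic", {
  p <- spread_params(m = 2, delta = 0, a = 0.3, N0 = 1e5, T = 6)
  counts <- vapply(1:2000, function(i) simulate_spread(p, seed = i)$n_colonies, 0L)
  mT <- 2 * 6
  se <- sqrt(mT / 2000)
  expect_lt(abs(mean(counts) - mT), 3 * se)

  pm0 <- spread_params(m = 0, delta = 2, a = 0.3, N0 = 1e5, T = 6)
  r0 <- simulate_spread(pm0, seed = 1)
  expect_identical(r0$n_colonies, 0L)
  expect_identical(r0$dtc_total, 0)

  # bit-for-bit determinism under a fixed seed
  pg <- spread_params(m = 0.1, delta = 1.5, a = 0.25, N0 = 1e4, T = 10)
  r1 <- simulate_spread(pg, seed = 99)
  r2 <- simulate_spread(pg, seed = 99)
  expect_identical(r1$colony_birth_times, r2$colony_birth_times)
  expect_identical(r1$dtc_total, r2$dtc_total)
})

test_that("simulator means match closed-form expectations (thinning and rescaling)", {
  pg <- spread_params(m = 0.1, delta = 1.2, a = 0.3, N0 = 1e4, T = 10)
  lam <- expected_colony_count(pg)
  D <- expected_total_dtc(pg)
  n_rep <- 1000
  res_t <- vapply(1:n_rep, function(i) {
    r <- simulate_spread(pg, seed = i)
    c(r$n_colonies, r$dtc_total)
  }, c(0, 0))
  expect_lt(abs(mean(res_t[1, ]) - lam), 3 * sqrt(lam / n_rep))
  sd_d <- sd(res_t[2, ])
  expect_lt(abs(mean(res_t[2, ]) - D), 3 * sd_d / sqrt(n_rep))

  res_r <- vapply(1:n_rep, function(i)
    simulate_spread(pg, seed = i, method = "rescale")$n_colonies, 0)
  expect_lt(abs(mean(res_r) - lam), 3 * sqrt(lam / n_rep))
})

test_that("calibration is linear in the target and self-inverse", {
  fit <- metaspread:::growth_fit(N0 = 2e6, a = 0.24, rss = 0, n_points = 5,
                                 rate_was_fixed = FALSE)
  m1 <- calibrate_colonization_coefficient(fit, T = 14, dtc_target = 1e4)
  m2 <- calibrate_colonization_coefficient(fit, T = 14, dtc_target = 2e4)
  expect_equal(m2, 2 * m1, tolerance = 1e-12)

  m_star <- 0.037
  D_fwd <- expected_total_dtc(spread_params(m = m_star, delta = 2, a = fit$a,
                                            N0 = fit$N0, T = 14))
  m_back <- calibrate_colonization_coefficient(fit, T = 14, dtc_target = D_fwd)
  expect_lt(abs(m_back - m_star) / m_star, 1e-10)

  expect_error(calibrate_colonization_coefficient(fit, T = 0, dtc_target = 10),
               "cannot calibrate")
})

test_that("delta inference from DTC round-trips, clamps, and is monotone", {
  fit <- metaspread:::growth_fit(N0 = 1e6, a = 0.26, rss = 0, n_points = 5,
                                 rate_was_fixed = FALSE)
  target <- expected_total_dtc(spread_params(m = 0.05, delta = 1.8, a = 0.26,
                                             N0 = 1e6, T = 14))
  rec <- infer_delta_from_dtc(fit, T = 14, m = 0.05, dtc_target = target)
  expect_lt(abs(rec$delta - 1.8), 1e-4)
  expect_false(rec$clamped)

  z <- infer_delta_from_dtc(fit, T = 14, m = 0.05, dtc_target = 0)
  expect_equal(z$delta, 0)
  expect_true(z$clamped)

  big <- infer_delta_from_dtc(fit, T = 14, m = 0.05, dtc_target = 1e30)
  expect_equal(big$delta, 3)
  expect_true(big$clamped)

  # monotone: a larger target never yields a smaller delta
  set.seed(5)
  for (i in 1:10) {
    t1 <- 10^runif(1, 2, 9); t2 <- t1 * runif(1, 1, 100)
    d1 <- infer_delta_from_dtc(fit, 14, 0.05, t1)$delta
    d2 <- infer_delta_from_dtc(fit, 14, 0.05, t2)$delta
    expect_gte(d2, d1 - 1e-9)
  }

  # identity on delta in (0,3): inference after forward model, random deltas
  for (d in c(0.4, 1.1, 2.2, 2.9)) {
    tg <- expected_total_dtc(spread_params(m = 0.05, delta = d, a = 0.26,
                                           N0 = 1e6, T = 14))
    expect_lt(abs(infer_delta_from_dtc(fit, 14, 0.05, tg)$delta - d), 1e-4)
  }
})

test_that("delta inference from CTC inverts the rate and both routes agree", {
  fit <- metaspread:::growth_fit(N0 = 1e6, a = 0.26, rss = 0, n_points = 5,
                                 rate_was_fixed = FALSE)
  xT <- 1e6 * exp(0.26 * 14)
  rate2 <- colonization_rate(xT, 0.05, 2)
  res <- infer_delta_from_ctc(fit, T = 14, m = 0.05, ctc_absolute_rate = rate2)
  expect_equal(res$delta, 2, tolerance = 1e-12)
  expect_false(res$clamped)

  expect_equal(infer_delta_from_ctc(fit, 14, 0.05, ctc_absolute_rate = 0)$delta, 0)
  expect_true(infer_delta_from_ctc(fit, 14, 0.05, ctc_absolute_rate = 0)$clamped)

  # cross-method consistency on noiseless forward-model data
  for (d in c(0.8, 1.6, 2.4)) {
    p <- spread_params(m = 0.05, delta = d, a = 0.26, N0 = 1e6, T = 14)
    d_dtc <- infer_delta_from_dtc(fit, 14, 0.05, expected_total_dtc(p))$delta
    d_ctc <- infer_delta_from_ctc(fit, 14, 0.05,
                                  ctc_absolute_rate = colonization_rate(
                                    p$N0 * exp(p$a * p$T), p$m, d))$delta
    expect_lt(abs(d_dtc - d_ctc), 0.05)
  }
})

test_that("DTC expectation is strictly increasing in delta, T, m, N0 and amplifies small delta changes", {
  base <- list(m = 0.05, a = 0.26, N0 = 1e6, T = 14)
  D <- function(delta = 2, m = base$m, a = base$a, N0 = base$N0, T = base$T)
    expected_total_dtc(spread_params(m = m, delta = delta, a = a, N0 = N0, T = T))
  deltas <- seq(0, 3, by = 0.25)
  expect_true(all(diff(vapply(deltas, function(d) D(delta = d), 0)) > 0))
  expect_true(all(diff(vapply(c(2, 5, 10, 20), function(T) D(T = T), 0)) > 0))
  expect_true(all(diff(vapply(c(0.01, 0.05, 0.2), function(m) D(m = m), 0)) > 0))
  expect_true(all(diff(vapply(c(1e4, 1e6, 1e8), function(n) D(N0 = n), 0)) > 0))

  # small changes of delta amplify dissemination strongly: an order of
  # magnitude between 1.5 and 2.0 at cohort scale, and growing with tumor size
  expect_gt(D(delta = 2.0) / D(delta = 1.5), 10)
  ratio_small <- D(delta = 2.0, N0 = 1e5) / D(delta = 1.5, N0 = 1e5)
  ratio_large <- D(delta = 2.0, N0 = 1e8) / D(delta = 1.5, N0 = 1e8)
  expect_gt(ratio_large, 2 * ratio_small)
})
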