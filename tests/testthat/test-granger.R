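make_latents <- function(N = 150, Tt = 30, phi = 0, couple = 0, lag = 2,
                         seed = 81) {
  set.seed(seed)
  Z1 <- matrix(rnorm(N * Tt), N, Tt)
  if (phi != 0)
    for (t in 2:Tt) Z1[, t] <- phi * Z1[, t - 1] + sqrt(1 - phi^2) * Z1[, t]
  Z2 <- matrix(rnorm(N * Tt), N, Tt)
  if (couple != 0)
    for (t in (lag + 1):Tt)
      Z2[, t] <- couple * Z1[, t - lag] + sqrt(1 - couple^2) * Z2[, t]
  list(Z1 = Z1, Z2 = Z2)
}

test_that("plug-in partial R2 equals the explicit regressions on every window", {
  lat <- make_latents(N = 120, Tt = 25, phi = 0.5, couple = 0.4)
  spec <- granger_spec(window_ms = 50, d_auto = 3, d_cross = 3, tau1 = 1,
                       tau2 = 3, fs = 100)
  for (t in c(5, 9, 14, 20, 25)) {
    for (resp in 1:2) {
      plug <- partial_r2(local_covariance(lat$Z1, lat$Z2, t, spec,
                                          response = resp), spec)
      ols <- ols_partial_r2(lat$Z1, lat$Z2, t, spec, response = resp)
      expect_lt(abs(plug - ols), 1e-10)
    }
  }
  ## also with a restricted delay range (tau2 < d_cross)
  spec2 <- granger_spec(window_ms = 50, d_auto = 3, d_cross = 3, tau1 = 2,
                        tau2 = 2, fs = 100)
  for (t in c(9, 16)) {
    plug <- partial_r2(local_covariance(lat$Z1, lat$Z2, t, spec2), spec2)
    expect_lt(abs(plug - ols_partial_r2(lat$Z1, lat$Z2, t, spec2)), 1e-10)
  }
})

test_that("local covariance recovers known structure", {
  lat <- make_latents(N = 400, Tt = 40, phi = 0.6, seed = 82)
  spec <- granger_spec(window_ms = 400, d_auto = 1, d_cross = 1, tau1 = 1,
                       tau2 = 1, fs = 100)
  C <- local_covariance(lat$Z1, lat$Z2, 20, spec)
  ## AR(1): lag-1 autocovariance is phi times the variance
  expect_equal(C[1, 2] / C[2, 2], 0.6, tolerance = 0.05)
  ## independent latents: cross entries near zero
  expect_lt(abs(C[1, 3]), 3 / sqrt(400 * spec$w_bins) * 3)
  ## full-trial window equals the global lag-augmented covariance
  spec_full <- granger_spec(window_ms = 1e5, d_auto = 1, d_cross = 1,
                            tau1 = 1, tau2 = 1, fs = 100)
  C1 <- local_covariance(lat$Z1, lat$Z2, 2, spec_full)
  C2 <- local_covariance(lat$Z1, lat$Z2, 39, spec_full)
  expect_equal(C1, C2, tolerance = 1e-12)
})

test_that("population-independent series give near-zero partial R2", {
  lat <- make_latents(N = 300, Tt = 30, seed = 83)
  spec <- granger_spec(window_ms = 100, d_auto = 2, d_cross = 2, tau1 = 1,
                       tau2 = 2, fs = 100)
  cur <- granger_curves(lat$Z1, lat$Z2, spec = spec)
  expect_true(all(cur$r2_12 >= 0 & cur$r2_12 <= 1))
  expect_lt(mean(cur$r2_12), 0.02)
})

test_that("directed coupling shows up in the right direction and swaps with the regions", {
  lat <- make_latents(N = 250, Tt = 30, phi = 0.3, couple = 0.5, lag = 2,
                      seed = 84)
  spec <- granger_spec(window_ms = 100, d_auto = 3, d_cross = 3, tau1 = 1,
                       tau2 = 3, fs = 100)
  cur <- granger_curves(lat$Z1, lat$Z2, spec = spec)
  expect_gt(mean(cur$r2_12), mean(cur$r2_21) + 0.05)
  swapped <- granger_curves(lat$Z2, lat$Z1, spec = spec)
  expect_equal(swapped$r2_21, cur$r2_12, tolerance = 1e-12)
  expect_equal(swapped$r2_12, cur$r2_21, tolerance = 1e-12)
})

test_that("single-lag partial R2 equals the squared recursive partial correlation", {
  lat <- make_latents(N = 300, Tt = 20, phi = 0.5, couple = 0.4, lag = 1,
                      seed = 85)
  spec <- granger_spec(window_ms = 10, d_auto = 1, d_cross = 1, tau1 = 1,
                       tau2 = 1, fs = 100)
  t <- 10
  C <- local_covariance(lat$Z2, lat$Z1, t, spec)   # response Z2
  plug <- partial_r2(C, spec)
  ## partial corr of (response, cross lag) given own lag, by the recursion
  R <- stats::cov2cor(C)
  r12.3 <- (R[1, 3] - R[1, 2] * R[3, 2]) /
    sqrt((1 - R[1, 2]^2) * (1 - R[3, 2]^2))
  expect_equal(plug, r12.3^2, tolerance = 1e-10)
})

test_that("the permutation null band is calibrated and preserves within-region structure", {
  lat <- make_latents(N = 200, Tt = 30, phi = 0.5, seed = 86)
  spec <- granger_spec(window_ms = 100, d_auto = 2, d_cross = 2, tau1 = 1,
                       tau2 = 2, fs = 100)
  cur <- granger_curves(lat$Z1, lat$Z2, spec = spec)
  band <- granger_null(lat$Z1, lat$Z2, spec = spec, n_perm = 60, seed = 87)
  frac <- mean(cur$r2_12 > band$null_12)
  expect_lt(frac, 0.25)          # null data exceed the 95% band rarely
  ## permuting trials leaves each region's own covariance unchanged (the
  ## same set of trials is pooled; only the summation order differs)
  perm <- sample(nrow(lat$Z2))
  C0 <- local_covariance(lat$Z2, lat$Z1, 15, spec)
  Cp <- local_covariance(lat$Z2[perm, , drop = FALSE], lat$Z1[perm, ], 15,
                         spec)
  expect_equal(C0[1:3, 1:3], Cp[1:3, 1:3], tolerance = 1e-12)
})

test_that("dominant excursions are located and scored correctly", {
  tms <- seq(0, 90, by = 10)
  curve <- c(0, 0, 3, 4, 3, 0, 0, 2, 0, 0)
  band <- rep(1, 10)
  e <- dominant_excursion(curve, band, tms)
  expect_equal(e$start_ms, 20)
  expect_equal(e$end_ms, 40)
  expect_equal(e$score, 2 + 3 + 2)
  expect_equal(e$center_ms, (2 * 20 + 3 * 30 + 2 * 40) / 7)
  expect_null(dominant_excursion(rep(0, 10), band, tms))
})
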