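test_that("electrode grid distances are Euclidean, symmetric and zero on the diagonal", {
  g <- electrode_grid(3, 3)
  expect_equal(nrow(g$positions), 9L)
  expect_true(all(diag(g$dist) == 0))
  expect_equal(g$dist, t(g$dist))
  i <- which(g$positions[, 1] == 1 & g$positions[, 2] == 1)
  j <- which(g$positions[, 1] == 3 & g$positions[, 2] == 3)
  expect_equal(g$dist[i, j], sqrt(8))
})

test_that("gaussian loading follows the spatial kernel", {
  g <- electrode_grid(3, 3)
  ctr <- which(g$positions[, 1] == 2 & g$positions[, 2] == 2)
  b <- gaussian_loading(g, c(2, 2), gamma = 0.077, sigma_spatial = 0.8)
  expect_equal(b[ctr], 0.077)                    # zero distance
  adj <- which(g$dist[, ctr] == 1)
  expect_equal(b[adj], rep(0.077 * exp(-1 / 1.28), length(adj)))
  ## kernel decay: the farthest corner is the smallest loading
  far <- which.max(g$dist[, ctr])
  expect_lt(b[far], min(b[adj]))
})

test_that("spatial noise correlation matches the Gaussian kernel within Monte-Carlo error", {
  g <- electrode_grid(3, 3)
  set.seed(42)
  x <- generate_noise(g, alpha = 1.4, sigma_spatial = 0.8, n_samples = 64,
                      n_trials = 1000, fs = 1000)
  ## pool samples over trials and times for each channel pair
  X <- matrix(x, ncol = 9)
  C <- stats::cor(X)
  K <- exp(-g$dist^2 / (2 * 0.8^2))
  n_eff <- nrow(X)
  for (i in 1:8) for (j in (i + 1):9) {
    se <- (1 - K[i, j]^2) / sqrt(n_eff)
    expect_lt(abs(C[i, j] - K[i, j]), 3 * se + 0.01)
  }
  ## reference value for an adjacent pair: exp(-1/(2*0.8^2)) ~ 0.458
  adj <- which(g$dist == 1, arr.ind = TRUE)[1, ]
  expect_equal(C[adj[1], adj[2]], exp(-1 / 1.28), tolerance = 0.05)
})

test_that("noise cross-channel correlation vanishes as sigma_spatial -> 0", {
  g <- electrode_grid(1, 2)
  set.seed(7)
  x <- generate_noise(g, alpha = 1.4, sigma_spatial = 1e-4, n_samples = 64,
                      n_trials = 600, fs = 1000)
  cc <- stats::cor(as.vector(x[, , 1]), as.vector(x[, , 2]))
  expect_lt(abs(cc), 0.02)
})

test_that("noise periodogram slope recovers -alpha", {
  g <- electrode_grid(1, 1)
  set.seed(9)
  alpha <- 1.4
  x <- generate_noise(g, alpha = alpha, sigma_spatial = 0.8, n_samples = 500,
                      n_trials = 500, fs = 1000)
  S <- 500
  pow <- rep(0, S)
  for (n in 1:500) pow <- pow + Mod(stats::fft(x[n, , 1]))^2
  freqs <- (seq_len(S) - 1) * 1000 / S
  keep <- freqs >= 10 & freqs <= 400       # central band
  fitl <- stats::lm(log(pow[keep]) ~ log(freqs[keep]))
  expect_equal(unname(stats::coef(fitl)[2]), -alpha, tolerance = 0.15)
})

test_that("noise rejects alpha <= 1 and short series", {
  g <- electrode_grid(2, 2)
  expect_error(generate_noise(g, alpha = 1, sigma_spatial = 0.8,
                              n_samples = 64, n_trials = 2, fs = 1000),
               "alpha")
  expect_error(generate_noise(g, alpha = 1.4, sigma_spatial = 0.8,
                              n_samples = 1, n_trials = 2, fs = 1000))
})

test_that("degenerate driver reduces to a pure windowed cosine", {
  d <- generate_driver(18, center_ms = 250, sd_ms = 1e9, n_samples = 500,
                       fs = 1000, n_trials = 2, amplitude = c(1, 1),
                       phase = c(0, 0))
  tt <- (0:499) / 1000
  expect_equal(d[1, ], cos(2 * pi * 18 * tt), tolerance = 1e-10)
  expect_equal(d[2, ], d[1, ])
})

test_that("stochastic driver envelope is localized at the epoch centre", {
  set.seed(3)
  d <- generate_driver(18, center_ms = 200, sd_ms = 35, n_samples = 500,
                       fs = 1000, n_trials = 300)
  prof <- colMeans(d^2)
  pk <- (which.max(prof) - 1)
  expect_lt(abs(pk - 200), 35)                       # within 1 envelope SD
  ## independent seeds give independent trials
  d2 <- generate_driver(18, 200, 35, 500, 1000, 300, seed = 1)
  d3 <- generate_driver(18, 200, 35, 500, 1000, 300, seed = 2)
  e2 <- rowMeans(d2[, 150:250]^2); e3 <- rowMeans(d3[, 150:250]^2)
  expect_lt(abs(stats::cor(e2, e3)), 0.15)
})

test_that("simulate is a pure function of its config", {
  cfg <- reduced_sim_config(n_trials = 10, seed = 5)
  a <- simulate_driver_model(cfg)
  b <- simulate_driver_model(cfg)
  expect_identical(unclass(a$L1), unclass(b$L1))
  expect_identical(unclass(a$L2), unclass(b$L2))
  ## and RNG state of the session is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_driver_model(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero coupling strength leaves pure noise", {
  cfg <- reduced_sim_config(n_trials = 150, gamma = 0, seed = 6)
  sim <- simulate_driver_model(cfg)
  e1 <- downsample(morlet_envelope(sim$L1, 18, 50), 100)
  e2 <- downsample(morlet_envelope(sim$L2, 18, 50), 100)
  ## envelope correlation across regions at the epoch times is null
  cc <- sapply(c(9, 21, 41), function(i) stats::cor(e1[, i, 5], e2[, i, 5]))
  expect_true(all(abs(cc) < 4 / sqrt(150)))
})

test_that("band SNR is monotone increasing in gamma", {
  snr <- vapply(c(0.055, 0.071, 0.089), function(g)
    estimate_snr(reduced_sim_config(n_trials = 60, gamma = g, seed = 8)),
    numeric(1))
  expect_true(all(diff(snr) > 0))
})

test_that("driver delays are applied with zero padding, not wrap-around", {
  x <- matrix(1:10, nrow = 1)
  sh <- ladyns:::shift_zero_pad(x, 3L)
  expect_equal(drop(sh), c(0, 0, 0, 1:7))
  sh2 <- ladyns:::shift_zero_pad(x, -2L)
  expect_equal(drop(sh2), c(3:10, 0, 0))
  expect_error(sim_config(lags_ms = rbind(c(0, 30, 600), c(30, 0, 0))),
               "lags")
})

test_that("latent recovery is exact for noiseless rank-one data", {
  set.seed(11)
  N <- 60; Tt <- 4; d <- 3
  Z <- matrix(rnorm(N * 2 * Tt), N, 2 * Tt)
  beta1 <- matrix(rnorm(Tt * d), Tt, d)
  beta2 <- matrix(rnorm(Tt * d), Tt, d)
  X1 <- array(0, c(N, Tt, d)); X2 <- array(0, c(N, Tt, d))
  for (t in 1:Tt) {
    X1[, t, ] <- outer(Z[, t], beta1[t, ])
    X2[, t, ] <- outer(Z[, Tt + t], beta2[t, ])
  }
  rec <- suppressWarnings(recover_true_latents(
    trial_tensor(X1, fs = 100), trial_tensor(X2, fs = 100),
    beta1, beta2, lambda_diag = 0))
  for (b in seq_len(2 * Tt)) {
    r <- abs(stats::cor(rec$Z[, b], Z[, b] - mean(Z[, b])))
    expect_gt(r, 1 - 1e-8)
  }
})

test_that("independent regions give a null cross block in the recovered precision", {
  set.seed(12)
  N <- 300; Tt <- 6; d <- 2
  X1 <- array(rnorm(N * Tt * d), c(N, Tt, d))
  X2 <- array(rnorm(N * Tt * d), c(N, Tt, d))
  b <- matrix(1, Tt, d)
  rec <- recover_true_latents(trial_tensor(X1, fs = 100),
                              trial_tensor(X2, fs = 100), b, b, 0.1)
  O12 <- rec$Omega_o[1:Tt, Tt + 1:Tt]
  expect_lt(max(abs(O12)), 4 / sqrt(N) * 1.5)
})

test_that("the true effect mask marks the designed epochs inside the band", {
  cfg <- reduced_sim_config(seed = 1)
  M <- true_effect_mask(cfg, fs_latent = 100, T_latent = 50, d_cross = 10)
  ## first epoch: region 1 near 80 ms, region 2 near 110 ms
  expect_true(M[9, 12])
  ## outside the band nothing is marked
  expect_false(any(M[abs(outer(1:50, 1:50, `-`)) > 10]))
  ## before the first epoch becomes active nothing is marked
  expect_false(any(M[1, ]))
})
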