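## Independent oracles and small fixtures used across the test files.

## ADMM solver for the entrywise-penalty graphical lasso: an independent
## algorithm (eigen-decomposition proximal steps) against which the
## block-coordinate solver is checked.
admm_pglasso <- function(S, Lambda, rho = 1, maxit = 5000, tol = 1e-10) {
  p <- nrow(S)
  hard <- is.infinite(Lambda)
  lam <- Lambda
  lam[hard] <- 0
  Z <- diag(p)
  U <- matrix(0, p, p)
  soft <- function(A, k) sign(A) * pmax(abs(A) - k, 0)
  for (it in seq_len(maxit)) {
    ev <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    d <- (ev$values + sqrt(ev$values^2 + 4 * rho)) / (2 * rho)
    Theta <- ev$vectors %*% (d * t(ev$vectors))
    Z_old <- Z
    Z <- soft(Theta + U, lam / rho)
    Z[hard] <- 0
    U <- U + Theta - Z
    if (max(abs(Z - Z_old)) < tol && max(abs(Theta - Z)) < tol) break
  }
  (Z + t(Z)) / 2
}

## random correlation-like PD matrix
rand_pd <- function(p, n = 5 * p) {
  A <- matrix(rnorm(n * p), n, p)
  stats::cov2cor(crossprod(A) / n + diag(0.5, p))
}

## random trial arrays with a shared latent at each time point
rand_coupled_arrays <- function(N, Tt, d1, d2 = d1, rho = 0.6, noise = 0.8) {
  Z1 <- matrix(rnorm(N * Tt), N, Tt)
  Z2 <- rho * Z1 + sqrt(1 - rho^2) * matrix(rnorm(N * Tt), N, Tt)
  X1 <- array(rnorm(N * Tt * d1) * noise, c(N, Tt, d1))
  X2 <- array(rnorm(N * Tt * d2) * noise, c(N, Tt, d2))
  for (t in seq_len(Tt)) {
    X1[, t, 1] <- X1[, t, 1] + Z1[, t]
    X2[, t, 1] <- X2[, t, 1] + Z2[, t]
    if (d1 > 1) X1[, t, 2] <- X1[, t, 2] + 0.5 * Z1[, t]
    if (d2 > 1) X2[, t, 2] <- X2[, t, 2] + 0.5 * Z2[, t]
  }
  list(X1 = X1, X2 = X2, Z1 = Z1, Z2 = Z2)
}

as_tensors <- function(arr_pair, fs = 100) {
  list(X1 = trial_tensor(arr_pair$X1, fs = fs),
       X2 = trial_tensor(arr_pair$X2, fs = fs))
}

## brute-force top canonical correlation over unit-variance weight pairs,
## parameterized by angles (d = 2 blocks only)
grid_cca_2d <- function(X1, X2, n_angle = 720) {
  S11 <- stats::cov(X1); S22 <- stats::cov(X2); S12 <- stats::cov(X1, X2)
  best <- 0
  ang <- seq(0, pi, length.out = n_angle)
  w_of <- function(theta, S) {
    w <- c(cos(theta), sin(theta))
    w / sqrt(drop(crossprod(w, S %*% w)))
  }
  for (a1 in ang) {
    w1 <- w_of(a1, S11)
    u <- drop(crossprod(w1, S12))          # 1 x 2
    ## best w2 for fixed w1 has closed form; grid only over w1
    v <- solve(S22, u)
    val <- sqrt(drop(crossprod(u, v)))
    if (val > best) best <- val
  }
  best
}

## connected components oracle on a lattice mask via igraph
igraph_clusters <- function(mask, adjacency = 4) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  key <- paste(idx[, 1], idx[, 2])
  edges <- NULL
  offs <- if (adjacency == 4) rbind(c(1, 0), c(0, 1)) else
    rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (o in seq_len(nrow(offs))) {
    nb <- cbind(idx[, 1] + offs[o, 1], idx[, 2] + offs[o, 2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= nrow(mask) & nb[, 2] >= 1 &
      nb[, 2] <= ncol(mask)
    ok[ok] <- mask[nb[ok, , drop = FALSE]]
    if (any(ok))
      edges <- rbind(edges, cbind(key[ok], paste(nb[ok, 1], nb[ok, 2])))
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = key))
  comp <- igraph::components(g)$membership
  lapply(split(names(comp), comp), function(k) {
    parts <- do.call(rbind, strsplit(k, " "))
    cbind(t = as.integer(parts[, 1]), s = as.integer(parts[, 2]))
  })
}

## canonical form for comparing cluster lists regardless of order
cluster_signature <- function(clusters) {
  unname(sort(vapply(clusters, function(cl)
    paste(sort(paste(cl[, 1], cl[, 2])), collapse = ";"), character(1))))
}

## explicit-regression partial R2 on the pooled, per-time-centred design --
## an independent route to the covariance plug-in
ols_partial_r2 <- function(Z1, Z2, t, spec, response = 1) {
  Zr <- if (response == 1) Z1 else Z2
  Zo <- if (response == 1) Z2 else Z1
  maxlag <- max(spec$d_auto, spec$d_cross)
  h <- spec$w_bins %/% 2L
  us <- max(maxlag + 1L, t - h):min(ncol(Z1), t + h)
  rows <- NULL
  for (u in us) {
    V <- cbind(Zr[, u], Zr[, u - seq_len(spec$d_auto)],
               Zo[, u - seq_len(spec$d_cross)])
    rows <- rbind(rows, sweep(V, 2, colMeans(V)))
  }
  y <- rows[, 1]
  auto <- rows[, 1 + seq_len(spec$d_auto), drop = FALSE]
  cross <- rows[, 1 + spec$d_auto + seq_len(spec$d_cross), drop = FALSE]
  keepx <- setdiff(seq_len(spec$d_cross), spec$tau1:spec$tau2)
  full <- stats::lm.fit(cbind(auto, cross), y)
  red <- stats::lm.fit(cbind(auto, cross[, keepx, drop = FALSE]), y)
  1 - sum(full$residuals^2) / sum(red$residuals^2)
}

## shared reduced-scale analysis fixture (computed once per test session)
.fixture_env <- new.env(parent = emptyenv())
reduced_fixture <- function(seed = 2024, B = 50) {
  key <- paste0("fix_", seed, "_", B)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- reduced_sim_config(seed = seed)
  sim <- simulate_driver_model(cfg)
  env1 <- downsample(morlet_envelope(sim$L1, cfg$f0, 50), 100)
  env2 <- downsample(morlet_envelope(sim$L2, cfg$f0, 50), 100)
  X1 <- center_trials(env1)$x
  X2 <- center_trials(env2)$x
  ld <- suppressWarnings(calibrate_lambda_diag(X1, X2, 50))$lambda_diag
  base <- penalty_spec(lambda_cross = 0, lambda_auto = 0,
                       lambda_diag = ld, d_cross = 10, d_auto = 10)
  lc <- calibrate_lambda_cross(X1, X2, base, grid = c(0.02, 0.05, 0.1, 0.2),
                               B = 10, seed = seed + 3)$lambda_cross
  pen <- penalty_spec(lambda_cross = lc, lambda_auto = 0,
                      lambda_diag = ld, d_cross = 10, d_auto = 10)
  fit <- ladyns(X1, X2, pen)
  inf <- ladyns_inference(X1, X2, fit, B = B, seed = seed + 1)
  out <- list(cfg = cfg, sim = sim, X1 = X1, X2 = X2, pen = pen,
              fit = fit, inf = inf)
  .fixture_env[[key]] <- out
  out
}

## weighted cluster summaries (centre time and lead-lag offset, ms)
cluster_measures <- function(inf, bin_ms = 10) {
  keep <- which(inf$cluster_table$p_value < 0.05)
  if (!length(keep)) return(NULL)
  out <- t(vapply(keep, function(k) {
    cl <- inf$clusters[[k]]
    tm <- (cl[, "t"] - 1) * bin_ms; sm <- (cl[, "s"] - 1) * bin_ms
    w <- -log(pmax(inf$pmap[cl], 1e-300))
    c(center_ms = sum(w * (tm + sm) / 2) / sum(w),
      lag_ms = sum(w * (tm - sm)) / sum(w))
  }, numeric(2)))
  out[order(out[, "center_ms"]), , drop = FALSE]
}
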