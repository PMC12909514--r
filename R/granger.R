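#' Moving-window specification for the locally stationary latent model
#'
#' The latent bivariate series is modelled as locally stationary: within
#' a moving window the lag-augmented latent vector is treated as
#' stationary, its covariance estimated by pooling lagged products
#' across trials and across the time points inside the window
#' (uniformly weighted).
#'
#' @param window_ms moving-window width, ms.
#' @param d_auto,d_cross maximal within-/cross-region lags, in bins.
#' @param tau1,tau2 minimum/maximum cross connection times in bins
#'   (`1 <= tau1 <= tau2 <= d_cross`); lags outside `[tau1, tau2]` are
#'   kept in the reduced regression so the partial R2 isolates the
#'   physiologically admissible delays.
#' @param fs sampling rate of the latent series, Hz.
#' @return a `granger_spec` list.
#' @export
granger_spec <- function(window_ms = 100, d_auto = 10L, d_cross = 10L,
                         tau1 = 1L, tau2 = d_cross, fs = 100) {
  stopifnot(window_ms > 0, d_auto >= 1, d_cross >= 1,
            tau1 >= 1, tau1 <= tau2, tau2 <= d_cross, fs > 0)
  w_bins <- max(1L, as.integer(round(window_ms / 1000 * fs)))
  structure(list(window_ms = window_ms, w_bins = w_bins,
                 d_auto = as.integer(d_auto), d_cross = as.integer(d_cross),
                 tau1 = as.integer(tau1), tau2 = as.integer(tau2), fs = fs),
            class = "granger_spec")
}

#' Pooled lag-augmented covariance around a window centre
#'
#' For response region `k` and window centre `t` (bin index), pools the
#' vectors `(Zk(u), Zk(u-1..u-d_auto), Zother(u-1..u-d_cross))` over all
#' trials and all valid `u` inside the window, and returns their
#' covariance. Windows are truncated at trial edges; an error is raised
#' if no valid time point remains.
#'
#' @param Z1,Z2 N x T latent matrices (trials by time).
#' @param t window centre, bin index.
#' @param spec a [granger_spec()].
#' @param response 1 or 2: which region is the regression response.
#' @return covariance matrix of dimension `1 + d_auto + d_cross`.
#' @export
local_covariance <- function(Z1, Z2, t, spec, response = 1) {
  stopifnot(inherits(spec, "granger_spec"), response %in% c(1, 2))
  Tt <- ncol(Z1)
  maxlag <- max(spec$d_auto, spec$d_cross)
  h <- spec$w_bins %/% 2L
  us <- max(maxlag + 1L, t - h):min(Tt, t + h)
  us <- us[us >= maxlag + 1L & us <= Tt]
  if (!length(us)) stop("window at t = ", t, " contains no valid time point")
  Zr <- if (response == 1) Z1 else Z2
  Zo <- if (response == 1) Z2 else Z1
  N <- nrow(Z1)
  if (N * length(us) < (1L + spec$d_auto + spec$d_cross) + 1L)
    stop("window underdetermined: too few trial x time samples")
  q <- 1L + spec$d_auto + spec$d_cross
  C <- matrix(0, q, q)
  for (u in us) {
    V <- cbind(Zr[, u],
               Zr[, u - seq_len(spec$d_auto), drop = FALSE],
               Zo[, u - seq_len(spec$d_cross), drop = FALSE])
    V <- sweep(V, 2L, colMeans(V))
    C <- C + crossprod(V) / (N - 1)
  }
  C / length(us)
}

#' Plug-in partial R2 from a lag-augmented covariance
#'
#' Coefficient of partial determination of the cross lags in
#' `[tau1, tau2]` for the response, computed from covariance blocks via
#' Schur complements -- algebraically identical to running the full and
#' reduced regressions. The full model conditions on all own lags and
#' all cross lags; the reduced model drops the cross lags inside
#' `[tau1, tau2]` but keeps those outside.
#'
#' @param C covariance from [local_covariance()] (response first, then
#'   `d_auto` own lags, then `d_cross` cross lags in lag order).
#' @param spec a [granger_spec()].
#' @return scalar partial R2 in `[0, 1]`.
#' @export
partial_r2 <- function(C, spec) {
  q <- 1L + spec$d_auto + spec$d_cross
  stopifnot(all(dim(C) == q))
  cross_of <- function(lags) 1L + spec$d_auto + lags
  full_pred <- c(1L + seq_len(spec$d_auto), cross_of(seq_len(spec$d_cross)))
  drop_lags <- spec$tau1:spec$tau2
  red_pred <- setdiff(full_pred, cross_of(drop_lags))
  rv_full <- resid_var(C, full_pred)
  rv_red <- resid_var(C, red_pred)
  if (rv_red <= 0) return(0)
  max(0, min(1, 1 - rv_full / rv_red))
}

## residual variance of component 1 given predictor set P (Schur complement)
resid_var <- function(C, P) {
  if (!length(P)) return(C[1, 1])
  CPP <- C[P, P, drop = FALSE]
  C1P <- C[1, P, drop = FALSE]
  sol <- tryCatch(solve(CPP, t(C1P)), error = function(e) {
    eps <- 1e-10 * sum(diag(CPP))
    warning("near-singular conditioning block; adding ridge ", signif(eps, 3))
    solve(CPP + diag(eps, nrow(CPP)), t(C1P))
  })
  drop(C[1, 1] - C1P %*% sol)
}

#' Time-resolved Granger partial R2 curves
#'
#' Computes the moving-window partial R2 in both directions at every
#' admissible window centre: `r2_12` is the influence of region 1 on
#' region 2 (cross lags of Z1 predicting Z2), `r2_21` the reverse.
#'
#' @param Z1,Z2 N x T latent matrices, or a `ladyns_fit` as `Z1` (its
#'   latents are split into the two regions and `fs` is taken from it).
#' @param spec a [granger_spec()].
#' @param t0_ms time stamp of bin 1 (ignored when a fit is supplied).
#' @return data.table with columns `t_bin`, `t_ms`, `r2_12`, `r2_21`.
#' @export
granger_curves <- function(Z1, Z2 = NULL, spec, t0_ms = 0) {
  if (inherits(Z1, "ladyns_fit")) {
    fit <- Z1
    Tt <- fit$T_len
    Z2 <- fit$latents[, Tt + seq_len(Tt), drop = FALSE]
    Z1 <- fit$latents[, seq_len(Tt), drop = FALSE]
    t0_ms <- fit$t0_ms
    if (!isTRUE(all.equal(spec$fs, fit$fs)))
      warning("granger_spec fs differs from the fit's latent sampling rate")
  }
  Tt <- ncol(Z1)
  maxlag <- max(spec$d_auto, spec$d_cross)
  h <- spec$w_bins %/% 2L
  ## edge windows are truncated: any centre whose window retains at least
  ## one admissible response time is kept
  centers <- (maxlag + 1L - h):Tt
  centers <- centers[centers >= 1L]
  r12 <- r21 <- numeric(length(centers))
  for (i in seq_along(centers)) {
    t <- centers[i]
    r21[i] <- partial_r2(local_covariance(Z1, Z2, t, spec, response = 1), spec)
    r12[i] <- partial_r2(local_covariance(Z1, Z2, t, spec, response = 2), spec)
  }
  data.table::data.table(t_bin = centers,
                         t_ms = t0_ms + (centers - 1) / spec$fs * 1000,
                         r2_12 = r12, r2_21 = r21)
}

#' Permutation null band for the Granger curves
#'
#' Repeatedly permutes the trial labels of region 2 (destroying the
#' cross-region pairing while preserving each region's autocorrelation
#' exactly), recomputes both partial-R2 curves, and returns the
#' pointwise `prob` quantile of the null distribution per direction.
#'
#' @inheritParams granger_curves
#' @param n_perm number of trial permutations.
#' @param prob quantile of the null band (default 0.95).
#' @param seed integer seed.
#' @return data.table with `t_bin`, `t_ms`, `null_12`, `null_21`.
#' @export
granger_null <- function(Z1, Z2 = NULL, spec, n_perm = 2000L, prob = 0.95,
                         seed = 1L, t0_ms = 0) {
  if (inherits(Z1, "ladyns_fit")) {
    fit <- Z1
    Tt <- fit$T_len
    Z2 <- fit$latents[, Tt + seq_len(Tt), drop = FALSE]
    Z1 <- fit$latents[, seq_len(Tt), drop = FALSE]
    t0_ms <- fit$t0_ms
  }
  stopifnot(n_perm >= 20L)
  seeds <- split_seed(seed, n_perm)
  r12 <- r21 <- NULL
  for (p in seq_len(n_perm)) {
    old <- get_rng_state(); set.seed(seeds[p])
    perm <- sample.int(nrow(Z2))
    restore_rng_state(old)
    cur <- granger_curves(Z1, Z2[perm, , drop = FALSE], spec, t0_ms)
    if (is.null(r12)) {
      r12 <- matrix(NA_real_, n_perm, nrow(cur))
      r21 <- matrix(NA_real_, n_perm, nrow(cur))
      tmpl <- cur
    }
    r12[p, ] <- cur$r2_12; r21[p, ] <- cur$r2_21
  }
  data.table::data.table(t_bin = tmpl$t_bin, t_ms = tmpl$t_ms,
                         null_12 = apply(r12, 2, stats::quantile, probs = prob),
                         null_21 = apply(r21, 2, stats::quantile, probs = prob))
}

#' Largest supra-null excursion of a Granger curve
#'
#' Finds contiguous runs where the observed curve exceeds the null band,
#' scores each by its summed exceedance, and returns the run with the
#' largest score together with its excess-weighted centre time.
#'
#' @param curve,band numeric vectors (observed curve and null band).
#' @param t_ms time stamps matching the vectors.
#' @return list with `center_ms`, `start_ms`, `end_ms`, `score`;
#'   `NULL` when the curve never exceeds the band.
#' @export
dominant_excursion <- function(curve, band, t_ms) {
  above <- curve > band
  if (!any(above)) return(NULL)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (i in which(r$values)) {
    idx <- starts[i]:ends[i]
    sc <- sum(curve[idx] - band[idx])
    if (is.null(best) || sc > best$score) {
      w <- curve[idx] - band[idx]
      best <- list(center_ms = sum(w * t_ms[idx]) / sum(w),
                   start_ms = t_ms[starts[i]], end_ms = t_ms[ends[i]],
                   score = sc)
    }
  }
  best
}
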