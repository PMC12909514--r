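#' Fit the latent dynamic pCCA model with a sparse banded precision
#'
#' Estimates, for two centred envelope tensors, one canonical weight
#' vector per region and time point together with a sparse banded
#' precision matrix of the 2T latent variables, by minimizing the
#' penalized negative log-likelihood
#' `-logdet(Omega) + tr(Omega Sigma_bar) + ||Lambda o Omega||_1`.
#' Coordinate descent alternates (i) an entrywise-penalty graphical
#' lasso ([pglasso()]) for `Omega` at fixed weights with (ii) exact
#' analytic updates of each weight `w_k(t)` at fixed `Omega` (the
#' quadratic objective in one weight under the unit-variance constraint
#' has closed form `w* = -V^{-1} c / sqrt(c' V^{-1} c)`). The latent
#' correlation `Sigma_bar` is recomputed, with unit-diagonal rescaling,
#' after each full weight sweep. The run is deterministic given the
#' initialization.
#'
#' @param X1,X2 centred [trial_tensor()]s (apply [center_trials()]
#'   first), N x T x d_k.
#' @param penalty a [penalty_spec()].
#' @param init `"cca"` (per-time CCA weights, the default), `"pca"`
#'   (first principal component per time), or a list of two d_k x T
#'   weight matrices.
#' @param tol convergence threshold on the absolute objective change.
#' @param max_iter cap on alternation cycles.
#' @param pg_tol,pg_maxit tolerances of the inner graphical-lasso solves.
#' @return a `ladyns_fit` object: weight matrices `w1`, `w2` (d_k x T),
#'   `Sigma_bar` (2T x 2T, unit diagonal), sparse `Omega_hat`, latent
#'   series `latents` (N x 2T), `objective_trace`, `converged`,
#'   `penalty`, plus the sampling metadata of the inputs.
#' @export
ladyns <- function(X1, X2, penalty, init = "cca", tol = 1e-3, max_iter = 500L,
                   pg_tol = 1e-5, pg_maxit = 500L) {
  stopifnot(inherits(X1, "trial_tensor"), inherits(X2, "trial_tensor"),
            inherits(penalty, "penalty_spec"))
  N <- n_trials(X1); Tt <- n_times(X1)
  stopifnot(n_trials(X2) == N, n_times(X2) == Tt, N >= 3)
  d <- c(n_channels(X1), n_channels(X2))
  p <- 2L * Tt
  Lambda <- build_penalty(Tt, penalty)

  ## per-(k,t) centred data blocks and covariance factors
  blocks <- vector("list", p)
  Vchol <- vector("list", p)
  for (k in 1:2) {
    Xk <- if (k == 1) X1 else X2
    for (t in seq_len(Tt)) {
      idx <- (k - 1L) * Tt + t
      Xb <- matrix(Xk[, t, ], N, d[k])
      Xb <- sweep(Xb, 2L, colMeans(Xb))
      blocks[[idx]] <- Xb
      Vchol[[idx]] <- safe_chol(crossprod(Xb) / (N - 1))
    }
  }

  W <- init_weights(blocks, Vchol, d, Tt, N, init)
  Z <- vapply(seq_len(p), function(b) blocks[[b]] %*% W[[b]], numeric(N))
  Sigma_bar <- stats::cov2cor(crossprod(Z) / (N - 1))

  trace <- numeric(0)
  warm <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pg <- pglasso(Sigma_bar, Lambda, warm = warm, tol = pg_tol,
                  maxit = pg_maxit, check_input = FALSE)
    warm <- pg
    Omega <- pg$Omega
    obj <- ladyns_objective(Omega, Sigma_bar, Lambda)
    if (!is.finite(obj))
      stop("non-finite objective at cycle ", it, "; check the inputs/penalty")
    trace <- c(trace, obj)
    if (it > 1L && abs(trace[it - 1L] - obj) < tol) { converged <- TRUE; break }

    ## analytic weight sweep: k = 1 then 2, t ascending
    for (b in seq_len(p)) {
      nz <- which(Omega[b, ] != 0)
      nz <- nz[nz != b]
      if (!length(nz)) next
      zw <- Z[, nz, drop = FALSE] %*% Omega[b, nz]
      cvec <- crossprod(blocks[[b]], zw) / (N - 1)
      if (sum(cvec^2) < 1e-24) next       # no coupling: keep previous weight
      R <- Vchol[[b]]
      q <- backsolve(R, backsolve(R, cvec, transpose = TRUE))
      nrm <- drop(crossprod(cvec, q))
      if (nrm <= 0) next
      W[[b]] <- -q / sqrt(nrm)
      Z[, b] <- blocks[[b]] %*% W[[b]]
    }
    Sigma_bar <- stats::cov2cor(crossprod(Z) / (N - 1))
  }
  if (!converged)
    warning("ladyns did not converge in ", max_iter, " cycles")

  ## reproducible sign convention: largest-|w| entry positive
  for (b in seq_len(p)) {
    i <- which.max(abs(W[[b]]))
    if (W[[b]][i] < 0) {
      W[[b]] <- -W[[b]]
      Z[, b] <- -Z[, b]
      Sigma_bar[b, ] <- -Sigma_bar[b, ]; Sigma_bar[, b] <- -Sigma_bar[, b]
      Omega[b, ] <- -Omega[b, ]; Omega[, b] <- -Omega[, b]
    }
  }

  structure(list(
    w1 = matrix(unlist(W[seq_len(Tt)]), d[1], Tt),
    w2 = matrix(unlist(W[Tt + seq_len(Tt)]), d[2], Tt),
    Sigma_bar = Sigma_bar, Omega_hat = Omega, latents = Z,
    objective_trace = trace, converged = converged, iterations = length(trace),
    penalty = penalty, init = if (is.character(init)) init else "custom",
    T_len = Tt, n_trials = N, fs = attr(X1, "fs"), t0_ms = attr(X1, "t0_ms")),
    class = "ladyns_fit")
}

#' @export
print.ladyns_fit <- function(x, ...) {
  cat(sprintf("ladyns_fit: T = %d, N = %d trials, d = (%d, %d)\n",
              x$T_len, x$n_trials, nrow(x$w1), nrow(x$w2)))
  cat(sprintf("  %d cycles (%sconverged), objective %.6f\n",
              x$iterations, if (x$converged) "" else "NOT ",
              utils::tail(x$objective_trace, 1)))
  nz <- sum(cross_block(x$Omega_hat, x$T_len) != 0)
  cat(sprintf("  nonzero cross-precision entries: %d\n", nz))
  invisible(x)
}

## extract the T x T cross block Omega_12 (rows: region 1, cols: region 2)
cross_block <- function(M, T_len) M[seq_len(T_len), T_len + seq_len(T_len)]

init_weights <- function(blocks, Vchol, d, Tt, N, init) {
  p <- 2L * Tt
  if (is.list(init)) {
    stopifnot(length(init) == 2L)
    W <- vector("list", p)
    for (k in 1:2) for (t in seq_len(Tt)) {
      b <- (k - 1L) * Tt + t
      w <- init[[k]][, t]
      V <- crossprod(Vchol[[b]])                  # R'R = V
      W[[b]] <- w / sqrt(drop(crossprod(w, V %*% w)))
    }
    return(W)
  }
  W <- vector("list", p)
  if (identical(init, "cca")) {
    for (t in seq_len(Tt)) {
      cc <- cca_pair(blocks[[t]], blocks[[Tt + t]])
      W[[t]] <- cc$w1; W[[Tt + t]] <- cc$w2
    }
  } else if (identical(init, "pca")) {
    for (b in seq_len(p)) {
      V <- crossprod(Vchol[[b]])
      ev <- eigen(V, symmetric = TRUE)
      w <- ev$vectors[, 1]
      W[[b]] <- fix_sign(w / sqrt(drop(crossprod(w, V %*% w))))
    }
  } else stop("unknown `init`: ", init)
  W
}
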