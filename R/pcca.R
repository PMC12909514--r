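#' Canonical correlation between two vector samples
#'
#' Top canonical pair of two data matrices observed at a single time
#' point, via the standard generalized eigenproblem (whitened SVD).
#' Weights are scaled to unit sample variance (`w' S_kk w = 1`) and the
#' sign is fixed so the largest-magnitude entry of each weight vector is
#' positive. A ridge `1e-8 * trace/d` is added (with a warning) when a
#' within-set covariance is numerically singular.
#'
#' @param X1,X2 N x d_k data matrices (rows are paired observations).
#' @return list with `w1`, `w2`, `sigma_cc`.
#' @export
cca_pair <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  stopifnot(nrow(X1) == nrow(X2))
  S11 <- stats::cov(X1); S22 <- stats::cov(X2)
  S12 <- stats::cov(X1, X2)
  R1 <- safe_chol(S11); R2 <- safe_chol(S22)
  K <- t(backsolve(R1, S12, transpose = TRUE))
  K <- t(backsolve(R2, K, transpose = TRUE))     # R1^-T S12 R2^-1
  sv <- svd(K, nu = 1, nv = 1)
  w1 <- backsolve(R1, sv$u[, 1])
  w2 <- backsolve(R2, sv$v[, 1])
  w1 <- fix_sign(w1); w2 <- fix_sign(w2)
  list(w1 = w1, w2 = w2,
       sigma_cc = abs(drop(crossprod(w1, S12 %*% w2))))
}

## Cholesky with a ridge fallback for singular covariances
safe_chol <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    eps <- 1e-8 * sum(diag(S)) / ncol(S)
    warning("singular within-set covariance; adding ridge ", signif(eps, 3))
    out <- chol(S + diag(eps, ncol(S)))
  }
  out
}

fix_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}

#' Probabilistic CCA maximum likelihood estimates
#'
#' Latent-variable formulation in which the two vectors share a
#' correlated pair of standard-normal factors. With the scale convention
#' `m1 = m2 = 1`, the loadings are `beta_k = S_kk w_k` and the latent
#' correlation `sigma_12` equals the canonical correlation, which this
#' function asserts numerically.
#'
#' @inheritParams cca_pair
#' @return list with `beta1`, `beta2`, `sigma12`, `m` and the underlying
#'   CCA solution.
#' @export
pcca_mle <- function(X1, X2) {
  cc <- cca_pair(X1, X2)
  S11 <- stats::cov(as.matrix(X1)); S22 <- stats::cov(as.matrix(X2))
  beta1 <- drop(S11 %*% cc$w1); beta2 <- drop(S22 %*% cc$w2)
  ## identity linking the two parameterizations
  stopifnot(abs(drop(crossprod(cc$w1, beta1)) - 1) < 1e-8)
  list(beta1 = beta1, beta2 = beta2, sigma12 = cc$sigma_cc,
       m = c(1, 1), cca = cc)
}

#' Generalized variance of a set of canonical variables
#'
#' The GENVAR multiset-CCA objective: the determinant of the (unit
#' diagonal) correlation matrix of all canonical variables.
#'
#' @param Sigma_bar correlation matrix of the canonical variables.
#' @export
genvar_objective <- function(Sigma_bar) {
  stopifnot(is.matrix(Sigma_bar), nrow(Sigma_bar) == ncol(Sigma_bar))
  if (max(abs(diag(Sigma_bar) - 1)) > 1e-6)
    stop("`Sigma_bar` must have unit diagonal")
  det(Sigma_bar)
}

#' GENVAR multiset CCA by generic numerical optimization
#'
#' Minimizes the generalized variance of the 2T canonical variables
#' `w_k(t)' X_k(t)` over all weights, with unit sample variance imposed
#' by reparameterization. This is a direct (quasi-Newton) optimizer over
#' an explicitly constructed objective, intended for small T as an
#' independent check of the coordinate-descent fit.
#'
#' @param X1,X2 arrays N x T x d_k.
#' @param init `"cca"` (per-time CCA weights) or a list of two d_k x T
#'   weight matrices.
#' @param maxit optimizer iteration cap.
#' @return list with weight matrices `w1`, `w2` (d_k x T), `Sigma_bar`,
#'   `objective` and the optimizer convergence code.
#' @export
multiset_cca_genvar <- function(X1, X2, init = "cca", maxit = 2000) {
  stopifnot(length(dim(X1)) == 3L, length(dim(X2)) == 3L)
  N <- dim(X1)[1]; Tt <- dim(X1)[2]
  d1 <- dim(X1)[3]; d2 <- dim(X2)[3]
  stopifnot(dim(X2)[1] == N, dim(X2)[2] == Tt)
  blocks <- c(lapply(seq_len(Tt), function(t) scale(matrix(X1[, t, ], N, d1), scale = FALSE)),
              lapply(seq_len(Tt), function(t) scale(matrix(X2[, t, ], N, d2), scale = FALSE)))
  if (identical(init, "cca")) {
    percca <- lapply(seq_len(Tt), function(t)
      cca_pair(matrix(X1[, t, ], N, d1), matrix(X2[, t, ], N, d2)))
    w0 <- c(unlist(lapply(percca, `[[`, "w1")),
            unlist(lapply(percca, `[[`, "w2")))
  } else {
    w0 <- c(as.vector(init[[1]]), as.vector(init[[2]]))
  }
  dims <- c(rep(d1, Tt), rep(d2, Tt))
  ends <- cumsum(dims); starts <- ends - dims + 1L
  obj <- function(v) {
    Z <- vapply(seq_along(blocks), function(b) {
      z <- blocks[[b]] %*% v[starts[b]:ends[b]]
      s <- sqrt(sum(z^2) / (N - 1))
      if (s == 0) return(rep(0, N))
      z / s
    }, numeric(N))
    determinant(crossprod(Z) / (N - 1), logarithm = TRUE)$modulus[1]
  }
  opt <- stats::optim(w0, obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  v <- opt$par
  W <- lapply(seq_along(blocks), function(b) {
    w <- v[starts[b]:ends[b]]
    Vb <- crossprod(blocks[[b]]) / (N - 1)
    fix_sign(w / sqrt(drop(crossprod(w, Vb %*% w))))
  })
  Z <- vapply(seq_along(blocks), function(b) blocks[[b]] %*% W[[b]],
              numeric(N))
  Sigma_bar <- stats::cov2cor(crossprod(Z) / (N - 1))
  list(w1 = matrix(unlist(W[seq_len(Tt)]), d1, Tt),
       w2 = matrix(unlist(W[Tt + seq_len(Tt)]), d2, Tt),
       Sigma_bar = Sigma_bar, objective = det(Sigma_bar),
       convergence = opt$convergence)
}
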