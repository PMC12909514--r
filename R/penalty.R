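#' Banded penalty specification
#'
#' Describes the entrywise penalty matrix Lambda that encodes both the
#' band constraints (entries outside the bands are penalized by `Inf`,
#' i.e. constrained to exactly zero) and the l1 penalties inside them.
#'
#' @param lambda_cross l1 penalty on off-diagonal cross-region precision
#'   entries (`k != l`, `0 < |t - s| <= d_cross`).
#' @param lambda_auto l1 penalty on off-diagonal within-region entries
#'   (`k = l`, `0 < |t - s| <= d_auto`); the recommended default is 0.
#' @param lambda_diag penalty on all `t = s` entries (diagonals of every
#'   block, including the simultaneous cross-precision); also the
#'   diagonal ridge added to the latent correlation before inversion.
#' @param d_cross,d_auto band half-widths in time bins.
#' @return a `penalty_spec` list.
#' @export
penalty_spec <- function(lambda_cross, lambda_auto = 0, lambda_diag = 0,
                         d_cross = 10L, d_auto = 10L) {
  stopifnot(lambda_cross >= 0, lambda_auto >= 0, lambda_diag >= 0,
            d_cross >= 0, d_auto >= 0)
  structure(list(lambda_cross = lambda_cross, lambda_auto = lambda_auto,
                 lambda_diag = lambda_diag,
                 d_cross = as.integer(d_cross), d_auto = as.integer(d_auto)),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf(paste0("penalty_spec: lambda_cross = %g, lambda_auto = %g, ",
                     "lambda_diag = %g, d_cross = %d, d_auto = %d\n"),
              x$lambda_cross, x$lambda_auto, x$lambda_diag, x$d_cross, x$d_auto))
  invisible(x)
}

#' Build the 2T x 2T penalty matrix
#'
#' Entry (in block form) is `lambda_cross` for off-diagonal cross entries
#' within the cross band, `lambda_auto` for off-diagonal within-region
#' entries within the auto band, `lambda_diag` whenever `t = s` (any
#' block), and `Inf` elsewhere.
#'
#' @param T_len number of latent time points per region.
#' @param spec a [penalty_spec()].
#' @return symmetric 2T x 2T penalty matrix.
#' @export
build_penalty <- function(T_len, spec) {
  stopifnot(inherits(spec, "penalty_spec"), T_len >= 1)
  lagd <- abs(outer(seq_len(T_len), seq_len(T_len), `-`))
  auto <- matrix(Inf, T_len, T_len)
  auto[lagd > 0 & lagd <= spec$d_auto] <- spec$lambda_auto
  diag(auto) <- spec$lambda_diag
  cross <- matrix(Inf, T_len, T_len)
  cross[lagd > 0 & lagd <= spec$d_cross] <- spec$lambda_cross
  diag(cross) <- spec$lambda_diag
  rbind(cbind(auto, cross), cbind(t(cross), auto))
}

#' Entrywise-penalty graphical lasso
#'
#' Minimizes `-logdet(Omega) + tr(Omega S) + sum(Lambda * |Omega|)` over
#' symmetric positive-definite matrices, with infinitely penalized
#' off-diagonal entries constrained to exactly zero, by block coordinate
#' descent (one row/column at a time, a lasso subproblem on the free
#' entries).
#'
#' @param S symmetric PSD input matrix (here: the latent correlation).
#' @param Lambda entrywise penalty matrix of the same size; `Inf` encodes
#'   hard zeros.
#' @param warm optional list with `W` and `B` from a previous solve.
#' @param tol convergence threshold on the working covariance update.
#' @param maxit maximum number of outer sweeps.
#' @param check_input verify symmetry and positive semi-definiteness of
#'   `S` (skipped inside the fit loop, whose inputs are Gram matrices).
#' @return list with `Omega`, working covariance `W`, regression
#'   coefficients `B`, `iterations` and a `converged` flag.
#' @export
pglasso <- function(S, Lambda, warm = NULL, tol = 1e-7, maxit = 500L,
                    check_input = TRUE) {
  p <- nrow(S)
  stopifnot(is.matrix(S), ncol(S) == p, is.matrix(Lambda),
            all(dim(Lambda) == p))
  if (check_input) {
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop("`S` must be symmetric")
    ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8 * max(1, max(abs(diag(S)))))
      stop("`S` must be positive semi-definite")
  }
  if (any(diag(S) + diag(Lambda) <= 0))
    stop("S + diag(Lambda) must have a positive diagonal")
  W0 <- if (!is.null(warm)) warm$W else S + diag(diag(Lambda), p)
  B0 <- if (!is.null(warm)) warm$B else matrix(0, p, p)
  res <- pglasso_cpp(S, Lambda, W0, B0, tol = tol, maxit = maxit,
                     inner_tol = tol / 10, inner_maxit = 200L)
  if (!res$converged)
    warning("pglasso did not converge within ", maxit, " sweeps")
  if (!res$pd)
    warning("pglasso recovery hit a non-positive pivot; result may be inaccurate")
  res
}

## penalized negative log-likelihood (the objective the fit minimizes);
## infinitely penalized entries are exactly zero and contribute nothing.
ladyns_objective <- function(Omega, Sigma_bar, Lambda) {
  ld <- determinant(Omega, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  fin <- is.finite(Lambda)
  -ld$modulus[1] + sum(Omega * Sigma_bar) + sum(Lambda[fin] * abs(Omega[fin]))
}
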