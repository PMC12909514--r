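#' Calibrate the diagonal regularizer from filter-induced autocorrelation
#'
#' Band-pass filtering makes the envelope series smooth, so the per-channel
#' T x T autocorrelation matrices `S_k,i` are near-singular and their
#' inverses are dominated by noise. This picks `lambda_diag` on a grid so
#' that the off-diagonal entries of `(S_k,i + lambda I)^-1`, after a
#' per-channel least-squares scale adjustment, are closest (in l2) to the
#' autocorrelation the filter kernel itself induces: for a complex Morlet
#' with envelope SD `sigma`, white noise acquires envelope autocorrelation
#' approximately `exp(-u^2 / (4 sigma^2))` at lag `u`.
#'
#' @param X1,X2 envelope [trial_tensor()]s (centred or not).
#' @param bandwidth_ms Morlet envelope SD used in preprocessing, ms.
#' @param grid candidate `lambda_diag` values (positive, increasing).
#' @return list with the selected `lambda_diag`, the per-grid summed
#'   distances, and a `boundary` flag set when the argmin sits on the
#'   grid edge.
#' @export
calibrate_lambda_diag <- function(X1, X2, bandwidth_ms,
                                  grid = 10^seq(-3, 0.5, length.out = 22)) {
  stopifnot(length(grid) >= 1, all(grid >= 0))
  grid <- sort(grid)
  fs <- attr(X1, "fs")
  Tt <- n_times(X1)
  u_ms <- abs(outer(time_ms(X1), time_ms(X1), `-`))
  R0 <- exp(-u_ms^2 / (4 * bandwidth_ms^2))
  off <- row(R0) != col(R0)
  b <- R0[off]
  Smats <- list()
  for (X in list(X1, X2)) for (i in seq_len(n_channels(X))) {
    Smats[[length(Smats) + 1L]] <- stats::cor(matrix(X[, , i], n_trials(X), Tt))
  }
  dist <- vapply(grid, function(lam) {
    tot <- 0
    for (S in Smats) {
      A <- solve(S + diag(lam, Tt))[off]
      sc <- sum(A * b) / sum(A * A)       # per-term optimal scalar
      tot <- tot + sum((sc * A - b)^2)
    }
    tot
  }, numeric(1))
  k <- which.min(dist)
  boundary <- k == 1L || k == length(grid)
  if (boundary && length(grid) > 1L)
    warning("lambda_diag argmin on the grid boundary; widen the grid")
  list(lambda_diag = grid[k], distances = dist, grid = grid,
       boundary = boundary)
}

#' Calibrate the cross penalty by controlling null discoveries
#'
#' Builds a trial-permuted dataset (region-2 trial labels shuffled, which
#' breaks all cross-region pairing), then runs the full fit-plus-inference
#' pipeline at each candidate `lambda_cross` and counts the significant
#' cross-precision discoveries, which are necessarily false. Returns the
#' smallest candidate yielding fewer discoveries than `max_false`; if none
#' qualifies, the largest candidate with a warning.
#'
#' @param X1,X2 centred envelope [trial_tensor()]s.
#' @param penalty [penalty_spec()] supplying the band widths,
#'   `lambda_auto` and `lambda_diag`; its `lambda_cross` is overridden by
#'   each grid value.
#' @param grid candidate `lambda_cross` values.
#' @param max_false discovery-count threshold (strictly fewer qualifies).
#' @param B bootstrap replicates used for the inference step at each
#'   candidate.
#' @param alpha_bh BH target FDR used when counting discoveries.
#' @param seed integer seed for the permutation and the bootstrap.
#' @param ... further arguments passed to [ladyns()].
#' @return list with `lambda_cross`, the per-candidate discovery counts,
#'   and the permutation used.
#' @export
calibrate_lambda_cross <- function(X1, X2, penalty, grid, max_false = 1L,
                                   B = 20L, alpha_bh = 0.05, seed = 1L, ...) {
  stopifnot(length(grid) >= 1)
  grid <- sort(grid)
  seeds <- split_seed(seed, 2L)
  old <- get_rng_state(); set.seed(seeds[1])
  perm <- sample.int(n_trials(X2))
  restore_rng_state(old)
  X2p <- tensor_like(unclass(X2)[perm, , , drop = FALSE], X2)
  counts <- integer(length(grid))
  chosen <- NA_real_
  for (g in seq_along(grid)) {
    pen <- penalty
    pen$lambda_cross <- grid[g]
    fit <- ladyns(X1, X2p, pen, ...)
    inf <- ladyns_inference(X1, X2p, fit, B = B, alpha_bh = alpha_bh,
                            seed = seeds[2])
    counts[g] <- sum(inf$discovered)
    if (is.na(chosen) && counts[g] < max_false) {
      chosen <- grid[g]
      ## larger penalties can only shrink the count further; stop here
      counts <- counts[seq_len(g)]
      break
    }
  }
  if (is.na(chosen)) {
    warning("no candidate met the false-discovery threshold; ",
            "returning the largest grid value")
    chosen <- grid[length(grid)]
  }
  list(lambda_cross = chosen, counts = counts,
       grid = grid[seq_along(counts)], permutation = perm)
}
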