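#' De-sparsify a penalized precision estimate
#'
#' Bias correction enabling entrywise Gaussian inference:
#' `Omega_tilde = 2 Omega_hat - Omega_hat (Sigma_bar + lambda_diag I) Omega_hat`.
#' When `Omega_hat = (Sigma_bar + lambda_diag I)^-1` (no l1 penalty) this
#' is a fixed point. The output is symmetrized against floating-point
#' asymmetry.
#'
#' @param Omega_hat,Sigma_bar 2T x 2T matrices (or a `ladyns_fit` as the
#'   first argument, in which case the rest is taken from the fit).
#' @param lambda_diag diagonal regularizer used in the fit.
#' @return the de-sparsified matrix `Omega_tilde`.
#' @export
desparsify <- function(Omega_hat, Sigma_bar = NULL, lambda_diag = 0) {
  if (inherits(Omega_hat, "ladyns_fit")) {
    fit <- Omega_hat
    return(desparsify(fit$Omega_hat, fit$Sigma_bar, fit$penalty$lambda_diag))
  }
  stopifnot(is.matrix(Omega_hat), all(dim(Omega_hat) == dim(Sigma_bar)))
  M <- Sigma_bar + diag(lambda_diag, nrow(Sigma_bar))
  Ot <- 2 * Omega_hat - Omega_hat %*% M %*% Omega_hat
  (Ot + t(Ot)) / 2
}

#' Permutation bootstrap of the de-sparsified cross-precision
#'
#' Generates `B` datasets satisfying the global null of no cross-region
#' association by permuting the trial labels of region 2 (trials are
#' exchangeable, so permuting one region is equivalent to permuting
#' both), refits the model with identical hyperparameters, and
#' de-sparsifies each replicate. The entrywise sample variance over
#' replicates estimates `Var[Omega_tilde_12(t, s)]` under the global
#' null. Replicates whose fit fails are dropped with a warning; fewer
#' than `B/2` successes is an error.
#'
#' @param X1,X2 the centred envelope tensors the fit was computed from.
#' @param fit the observed-data `ladyns_fit` (supplies penalty, init,
#'   tolerance).
#' @param B number of bootstrap replicates.
#' @param seed integer seed; split per replicate.
#' @param tol,max_iter fit controls for the replicates (defaults mirror
#'   the observed fit).
#' @return list with `Omega_tilde_12` (T x T x B array), `var_hat`
#'   (T x T), and the number of successful replicates.
#' @export
permutation_bootstrap <- function(X1, X2, fit, B = 200L, seed = 1L,
                                  tol = 1e-3, max_iter = 500L) {
  stopifnot(B >= 2L, inherits(fit, "ladyns_fit"))
  N <- n_trials(X2); Tt <- fit$T_len
  seeds <- split_seed(seed, B)
  reps <- array(NA_real_, dim = c(Tt, Tt, B))
  ok <- logical(B)
  for (b in seq_len(B)) {
    old <- get_rng_state(); set.seed(seeds[b])
    perm <- sample.int(N)
    restore_rng_state(old)
    X2p <- tensor_like(unclass(X2)[perm, , , drop = FALSE], X2)
    res <- tryCatch({
      fb <- suppressWarnings(ladyns(X1, X2p, fit$penalty, init = fit$init,
                                    tol = tol, max_iter = max_iter))
      cross_block(desparsify(fb), Tt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("bootstrap replicate ", b, " failed: ", conditionMessage(res))
    } else {
      reps[, , b] <- res; ok[b] <- TRUE
    }
  }
  if (sum(ok) < B / 2)
    stop("more than half of the bootstrap replicates failed")
  reps <- reps[, , ok, drop = FALSE]
  var_hat <- apply(reps, c(1, 2), stats::var)
  list(Omega_tilde_12 = reps, var_hat = var_hat, n_success = sum(ok))
}

#' Entrywise p-values for the cross-precision
#'
#' Two-sided Gaussian p-values `2 - 2 Phi(|Omega_tilde| / sqrt(var))`
#' over the region of interest; entries with zero variance are untestable
#' and receive p = 1 with a warning.
#'
#' @param Omega_tilde_12 T x T de-sparsified cross block.
#' @param var_hat T x T bootstrap variances.
#' @param roi logical T x T region-of-interest mask (`NULL` = all).
#' @return T x T matrix of p-values (NA outside the ROI).
#' @export
precision_pvalues <- function(Omega_tilde_12, var_hat, roi = NULL) {
  stopifnot(all(dim(Omega_tilde_12) == dim(var_hat)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(var_hat), ncol(var_hat))
  p <- matrix(NA_real_, nrow(var_hat), ncol(var_hat))
  bad <- roi & (var_hat <= 0)
  if (any(bad)) {
    warning(sum(bad), " ROI entries have zero bootstrap variance; p set to 1")
    p[bad] <- 1
  }
  okm <- roi & var_hat > 0
  p[okm] <- 2 - 2 * stats::pnorm(abs(Omega_tilde_12[okm]) / sqrt(var_hat[okm]))
  p
}

#' Benjamini-Hochberg step-up selection
#'
#' Standard BH on the ROI p-values: finds the largest `k` with
#' `p_(k) <= k alpha / n_roi`; entries with p strictly below the
#' resulting threshold `k alpha / n_roi` are discovered.
#'
#' @param pmap p-value matrix (NA outside the ROI).
#' @param alpha_bh target false discovery rate.
#' @return list with `k_bh`, `threshold`, logical `discovered` mask and
#'   `n_roi`.
#' @export
bh_select <- function(pmap, alpha_bh = 0.05) {
  pv <- pmap[!is.na(pmap)]
  n <- length(pv)
  stopifnot(n >= 1)
  ps <- sort(pv)
  k <- which(ps <= seq_len(n) / n * alpha_bh)
  k_bh <- if (length(k)) max(k) else 0L
  thr <- k_bh * alpha_bh / n
  disc <- !is.na(pmap) & pmap < thr
  list(k_bh = k_bh, threshold = thr, discovered = disc, n_roi = n)
}

#' Connected clusters of discovered entries
#'
#' Maximal connected components of the discovery mask on the (t, s)
#' lattice under 4-neighbourhood adjacency (diagonal-touching blobs stay
#' separate; set `adjacency = 8` to merge them). No cluster-forming
#' threshold or minimum size beyond the mask itself.
#'
#' @param mask logical T x T matrix.
#' @param adjacency 4 or 8.
#' @return list of clusters, each an integer matrix with columns `t`, `s`.
#' @export
form_clusters <- function(mask, adjacency = 4) {
  stopifnot(is.matrix(mask), adjacency %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (adjacency == 4) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    as.matrix(expand.grid(dr = -1:1, ds = -1:1)[-5, ])
  }
  cur <- 0L
  clusters <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!isTRUE(mask[i, j]) || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- cur
    members <- queue
    while (nrow(queue)) {
      cell <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (q in seq_len(nrow(nbr))) {
        r <- cell[1] + nbr[q, 1]; s <- cell[2] + nbr[q, 2]
        if (r >= 1 && r <= nr && s >= 1 && s <= nc &&
            isTRUE(mask[r, s]) && lab[r, s] == 0L) {
          lab[r, s] <- cur
          queue <- rbind(queue, c(r, s))
          members <- rbind(members, c(r, s))
        }
      }
    }
    colnames(members) <- c("t", "s")
    clusters[[cur]] <- members
  }
  clusters
}

#' Cluster-wise excursion test
#'
#' Fisher-style cluster statistic `T_k = -2 sum log p(t, s)` over each
#' cluster, referred to the permutation null of the maximum: every null
#' replicate is thresholded at the observed-data BH threshold, its
#' clusters formed the same way, and `T_max^b` recorded (0 when a
#' replicate has no clusters, which makes the empirical tail well
#' defined). The cluster p-value is the proportion of null maxima at or
#' above `T_k`; exact zeros should be reported as `< 1/B`.
#'
#' @param clusters list of cluster index matrices (from [form_clusters()]).
#' @param pmap observed p-value matrix.
#' @param null_pmaps T x T x B array of null-replicate p-values.
#' @param threshold BH threshold from the observed data.
#' @param roi logical ROI mask used for the null replicates.
#' @param adjacency cluster adjacency, as in [form_clusters()].
#' @return list with `T_k`, cluster `p_values` and the null maxima
#'   `Tmax_null`.
#' @export
excursion_test <- function(clusters, pmap, null_pmaps, threshold,
                           roi = NULL, adjacency = 4) {
  B <- dim(null_pmaps)[3]
  if (is.null(B) || B < 1L) stop("need at least one null replicate")
  T_k <- vapply(clusters, function(cl)
    -2 * sum(log(pmax(pmap[cl], .Machine$double.xmin))), numeric(1))
  Tmax <- numeric(B)
  for (b in seq_len(B)) {
    pb <- null_pmaps[, , b]
    mb <- !is.na(pb) & pb < threshold
    if (!is.null(roi)) mb <- mb & roi
    if (!any(mb)) { Tmax[b] <- 0; next }
    cls <- form_clusters(mb, adjacency)
    Tmax[b] <- max(vapply(cls, function(cl)
      -2 * sum(log(pmax(pb[cl], .Machine$double.xmin))), numeric(1)))
  }
  pvals <- vapply(T_k, function(tk) mean(Tmax >= tk), numeric(1))
  list(T_k = T_k, p_values = pvals, Tmax_null = Tmax)
}

#' Full inference pipeline for a fitted model
#'
#' De-sparsifies the fit, runs the trial-permutation bootstrap, computes
#' entrywise p-values over the banded region of interest, applies BH
#' selection, forms clusters and attaches excursion p-values.
#'
#' @inheritParams permutation_bootstrap
#' @param alpha_bh BH target FDR.
#' @param adjacency cluster adjacency (4 or 8).
#' @param include_diag keep the `t = s` diagonal inside the ROI.
#' @param seed integer seed for the bootstrap.
#' @return an `inference_result`: `Omega_tilde`, `var_hat`, `pmap`,
#'   `roi`, `n_roi`, `k_bh`, `bh_threshold`, `discovered`, `clusters`,
#'   a `cluster_table` (data.table), `Tmax_null` and settings.
#' @export
ladyns_inference <- function(X1, X2, fit, B = 200L, alpha_bh = 0.05,
                             adjacency = 4, include_diag = TRUE, seed = 1L,
                             tol = 1e-3, max_iter = 500L) {
  Tt <- fit$T_len
  Ot <- desparsify(fit)
  Ot12 <- cross_block(Ot, Tt)
  boot <- permutation_bootstrap(X1, X2, fit, B = B, seed = seed,
                                tol = tol, max_iter = max_iter)
  lagd <- abs(outer(seq_len(Tt), seq_len(Tt), `-`))
  roi <- lagd <= fit$penalty$d_cross
  if (!include_diag) roi <- roi & lagd > 0
  pmap <- precision_pvalues(Ot12, boot$var_hat, roi)
  bh <- bh_select(pmap, alpha_bh)
  clusters <- form_clusters(bh$discovered, adjacency)
  Bok <- dim(boot$Omega_tilde_12)[3]
  null_pmaps <- array(NA_real_, c(Tt, Tt, Bok))
  for (b in seq_len(Bok))
    null_pmaps[, , b] <- suppressWarnings(
      precision_pvalues(boot$Omega_tilde_12[, , b], boot$var_hat, roi))
  exc <- if (length(clusters) && bh$threshold > 0) {
    excursion_test(clusters, pmap, null_pmaps, bh$threshold, roi, adjacency)
  } else list(T_k = numeric(0), p_values = numeric(0),
              Tmax_null = numeric(0))
  tms <- fit$t0_ms + (seq_len(Tt) - 1) / fit$fs * 1000
  bin_ms <- 1000 / fit$fs
  tab <- if (length(clusters)) {
    data.table::rbindlist(lapply(seq_along(clusters), function(k) {
      cl <- clusters[[k]]
      wgt <- abs(Ot12[cl])
      if (sum(wgt) <= 0) wgt <- rep(1, nrow(cl))
      data.table::data.table(
        cluster_id = k, size = nrow(cl),
        t_min_ms = min(tms[cl[, "t"]]), t_max_ms = max(tms[cl[, "t"]]),
        s_min_ms = min(tms[cl[, "s"]]), s_max_ms = max(tms[cl[, "s"]]),
        center_ms = mean((tms[cl[, "t"]] + tms[cl[, "s"]]) / 2),
        mean_lag_ms = sum(wgt * (cl[, "t"] - cl[, "s"])) / sum(wgt) * bin_ms,
        T_k = exc$T_k[k], p_value = exc$p_values[k])
    }))
  } else data.table::data.table()
  structure(list(Omega_tilde = Ot, var_hat = boot$var_hat, pmap = pmap,
                 roi = roi, n_roi = bh$n_roi, k_bh = bh$k_bh,
                 bh_threshold = bh$threshold, discovered = bh$discovered,
                 clusters = clusters, cluster_table = tab,
                 Tmax_null = exc$Tmax_null, null_pmaps = null_pmaps,
                 B = Bok, alpha_bh = alpha_bh, adjacency = adjacency,
                 seed = seed),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("inference_result: %d ROI entries, BH k = %d (threshold %.3g), %d cluster(s)\n",
              x$n_roi, x$k_bh, x$bh_threshold, length(x$clusters)))
  if (nrow(x$cluster_table)) {
    tab <- data.table::copy(x$cluster_table)
    tab$p_value <- ifelse(tab$p_value == 0, paste0("<", signif(1 / x$B, 2)),
                          format(tab$p_value, digits = 3))
    print(tab)
  }
  invisible(x)
}

#' Cluster-level recovery metrics against a known truth
#'
#' A discovered cluster is falsely discovered if it overlaps no entry of
#' the true-effect mask; a true cluster (connected component of the
#' mask) is falsely non-discovered if no discovered cluster overlaps it.
#' FCDR = false discoveries / max(#discovered, 1);
#' FCNR = missed true clusters / #true clusters.
#'
#' @param clusters list of discovered clusters ([form_clusters()] output).
#' @param true_mask logical T x T ground-truth effect mask.
#' @param adjacency adjacency used to split the truth into clusters.
#' @return list with `fcdr`, `fcnr`, counts and per-cluster overlap flags.
#' @export
evaluate_recovery <- function(clusters, true_mask, adjacency = 4) {
  true_clusters <- form_clusters(true_mask, adjacency)
  overlaps <- vapply(clusters, function(cl) any(true_mask[cl]), logical(1))
  n_disc <- length(clusters)
  fcdr <- sum(!overlaps) / max(n_disc, 1)
  hit <- vapply(true_clusters, function(tc) {
    any(vapply(clusters, function(cl) {
      key_cl <- paste(cl[, 1], cl[, 2])
      key_tc <- paste(tc[, 1], tc[, 2])
      any(key_cl %in% key_tc)
    }, logical(1)))
  }, logical(1))
  fcnr <- if (length(true_clusters)) sum(!hit) / length(true_clusters) else 0
  list(fcdr = fcdr, fcnr = fcnr, n_discovered = n_disc,
       n_true = length(true_clusters), discovered_is_true = overlaps,
       true_is_found = hit)
}
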