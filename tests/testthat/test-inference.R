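test_that("p-values follow the two-sided Gaussian tail", {
  v <- matrix(1, 2, 2)
  O <- matrix(c(0, 1.959964, -1.959964, 5), 2, 2)
  p <- precision_pvalues(O, v)
  expect_equal(p[1, 1], 1)
  expect_equal(p[1, 2], 0.05, tolerance = 1e-6)
  expect_equal(p[2, 1], 0.05, tolerance = 1e-6)
  expect_lt(p[2, 2], 1e-6)
  ## strictly decreasing in |Omega| at fixed variance
  z <- seq(0, 4, by = 0.5)
  pv <- precision_pvalues(matrix(z, 1), matrix(1, 1, length(z)))
  expect_true(all(diff(drop(pv)) < 0))
  ## zero variance is flagged and untestable
  expect_warning(p0 <- precision_pvalues(matrix(1), matrix(0)), "zero")
  expect_equal(p0[1, 1], 1)
})

test_that("BH step-up matches a hand-worked example", {
  p <- matrix(c(0.001, 0.010, 0.030, 0.040, 0.800), 1)
  sel <- bh_select(p, alpha_bh = 0.05)
  expect_equal(sel$k_bh, 4L)
  expect_equal(sel$threshold, 4 * 0.05 / 5)
  ## rejection is strict (p *smaller than* the threshold), so the entry
  ## sitting exactly at the threshold is not discovered
  expect_equal(sum(sel$discovered), 3L)
  expect_false(sel$discovered[1, 4])
  none <- bh_select(matrix(1, 2, 2), 0.05)
  expect_equal(sum(none$discovered), 0L)
})

test_that("BH controls the FDR on uniform null p-values", {
  set.seed(71)
  n <- 100; reps <- 500
  fdp <- replicate(reps, {
    sel <- bh_select(matrix(stats::runif(n), 1), alpha_bh = 0.05)
    if (sum(sel$discovered) > 0) 1 else 0    # all discoveries are false
  })
  mcse <- stats::sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), 0.05 + 3 * mcse)
})

test_that("cluster formation matches adjacency conventions and an igraph oracle", {
  skip_if_not_installed("igraph")
  expect_equal(form_clusters(matrix(FALSE, 3, 3)), list())
  ## two diagonal-touching entries: separate under 4, joined under 8
  m <- matrix(FALSE, 3, 3); m[1, 1] <- m[2, 2] <- TRUE
  expect_length(form_clusters(m, 4), 2L)
  expect_length(form_clusters(m, 8), 1L)
  ## an L-shaped blob is one cluster of size 4
  L <- matrix(FALSE, 5, 5)
  L[cbind(c(2, 3, 4, 4), c(2, 2, 2, 3))] <- TRUE
  cl <- form_clusters(L, 4)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1]]), 4L)
  ## random masks against the independent graph-component oracle
  set.seed(72)
  for (rep in 1:5) for (adj in c(4, 8)) {
    m <- matrix(stats::runif(100) < 0.35, 10, 10)
    expect_equal(cluster_signature(form_clusters(m, adj)),
                 cluster_signature(igraph_clusters(m, adj)))
  }
})

test_that("excursion statistics behave at the boundaries", {
  pmap <- matrix(1, 4, 4)
  clusters <- list(cbind(t = 2L, s = 2L))
  nulls <- array(stats::runif(16 * 20), c(4, 4, 20))
  ex <- excursion_test(clusters, pmap, nulls, threshold = 0.5)
  expect_equal(ex$T_k, 0)
  expect_equal(ex$p_values, 1)      # every null maximum is >= 0
  ## a huge cluster statistic is never exceeded
  pmap2 <- matrix(1e-300, 4, 4)
  ex2 <- excursion_test(list(which(pmap2 < 1, arr.ind = TRUE)), pmap2,
                        nulls, threshold = 1e-4)
  expect_equal(ex2$p_values, 0)
  ## with no clusters in a null replicate, its maximum is zero
  expect_true(all(ex$Tmax_null >= 0))
})

test_that("excursion p-values are invariant to cluster and replicate order", {
  set.seed(73)
  pmap <- matrix(stats::runif(25, 0, 0.2), 5, 5)
  nulls <- array(stats::runif(25 * 30), c(5, 5, 30))
  cl <- list(cbind(t = c(1L, 2L), s = c(1L, 1L)), cbind(t = 4L, s = 4L))
  a <- excursion_test(cl, pmap, nulls, 0.3)
  b <- excursion_test(rev(cl), pmap, nulls[, , sample(30)], 0.3)
  expect_equal(a$p_values, rev(b$p_values))
  ## growing a cluster can only increase its statistic
  cl_big <- list(rbind(cl[[1]], cbind(t = 3L, s = 1L)))
  expect_gt(excursion_test(cl_big, pmap, nulls, 0.3)$T_k, a$T_k[1])
})

test_that("recovery metrics count false and missed clusters correctly", {
  truth <- matrix(FALSE, 6, 6); truth[2:3, 2:3] <- TRUE
  hit <- list(cbind(t = 2L, s = 2L))
  miss <- list(cbind(t = 6L, s = 6L))
  both <- c(hit, miss)
  expect_equal(evaluate_recovery(hit, truth)[c("fcdr", "fcnr")],
               list(fcdr = 0, fcnr = 0))
  expect_equal(evaluate_recovery(list(), truth)[c("fcdr", "fcnr")],
               list(fcdr = 0, fcnr = 1))
  r <- evaluate_recovery(both, truth)
  expect_equal(r$fcdr, 0.5)
  expect_equal(r$fcnr, 0)
})

test_that("the bootstrap yields positive variances and inference plumbing holds together", {
  set.seed(74)
  pair <- rand_coupled_arrays(80, 4, 2, 2, rho = 0.5)
  tens <- as_tensors(pair)
  pen <- penalty_spec(0.02, 0, 0.3, d_cross = 2, d_auto = 2)
  fit <- ladyns(tens$X1, tens$X2, pen)
  inf <- ladyns_inference(tens$X1, tens$X2, fit, B = 12, seed = 75)
  expect_true(all(inf$var_hat[inf$roi] > 0))
  expect_true(all(inf$pmap[inf$roi] >= 0 & inf$pmap[inf$roi] <= 1))
  expect_true(all(is.na(inf$pmap[!inf$roi])))
  expect_equal(inf$n_roi, sum(inf$roi))
  expect_true(all(!inf$discovered[!inf$roi]))
  ## clusters partition the discovered set
  expect_equal(sum(vapply(inf$clusters, nrow, integer(1))),
               sum(inf$discovered))
  ## ROI excludes the diagonal on request
  inf2 <- ladyns_inference(tens$X1, tens$X2, fit, B = 5, seed = 76,
                           include_diag = FALSE)
  expect_true(all(!diag(inf2$roi)))
})
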