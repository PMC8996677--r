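test_that("sample covariance standardizes to a correlation matrix", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 5)  # perfectly correlated
  S <- sample_covariance(x)
  expect_equal(S[1, 2], 1)
  expect_equal(diag(S), c(a = 1, b = 1), tolerance = 1e-12)

  set.seed(1)
  n <- 4000
  X <- matrix(rnorm(n * 5), n)
  S2 <- sample_covariance(X)
  expect_lt(max(abs(S2[upper.tri(S2)])), 4 / sqrt(n))

  X0 <- cbind(rnorm(10), rep(1, 10))
  expect_error(sample_covariance(X0), "zero-variance")
  expect_error(sample_covariance(X[1, , drop = FALSE]), "2 subjects")
})

test_that("graphical lasso solves the penalized likelihood", {
  # dominant penalty: empty graph
  S <- matrix(c(1, .3, .2, .3, 1, .25, .2, .25, 1), 3)
  f <- graphical_lasso(S, lambda = 0.35)
  expect_true(all(f$theta[upper.tri(f$theta)] == 0))

  # lambda = 0 with n > p: the unpenalized MLE solve(S)
  set.seed(2)
  X <- matrix(rnorm(60 * 8), 60)
  Se <- cov(X)
  f0 <- graphical_lasso(Se, 0)
  expect_lt(max(abs(f0$theta - solve(Se))), 1e-6)

  # 2x2 case against a direct numerical maximizer
  S2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  f2 <- graphical_lasso(S2, 0.2, tol = 1e-7)
  oracle <- oracle_glasso_2x2(S2, 0.2)
  expect_lt(max(abs(f2$theta - oracle)), 1e-5)
  # the implied covariance soft-thresholds the 0.6 entry toward 0.4
  expect_equal(solve(f2$theta)[1, 2], 0.4, tolerance = 1e-4)

  # every returned precision is positive definite (Cholesky succeeds)
  # and satisfies the KKT conditions within tolerance
  set.seed(3)
  for (r in 1:10) {
    p <- sample(4:12, 1)
    Xr <- matrix(rnorm(50 * p), 50)
    Sr <- sample_covariance(Xr)
    fr <- graphical_lasso(Sr, runif(1, 0.05, 0.5))
    expect_silent(chol(fr$theta))
    expect_lt(fr$kkt, 1e-3)
    expect_equal(max(abs(fr$theta - t(fr$theta))), 0)
  }

  expect_error(graphical_lasso(matrix(c(1, .5, .2, 1), 2), 0.1), "symmetric")
  expect_error(graphical_lasso(S2, -1), "lambda")
})

test_that("density-targeted penalty search brackets the requested sparsity", {
  set.seed(4)
  spec <- make_sparse_precision(20, 0.10, n_hubs = 2, seed = 4)
  x <- sample_suvr_matrix(spec, 400, seed = 5)
  S <- sample_covariance(x)

  r0 <- lambda_for_density(S, 0)
  expect_equal(r0$density, 0)

  r <- lambda_for_density(S, 0.10)
  expect_gte(r$density, 0.08)
  expect_lte(r$density, 0.12)

  # density is non-increasing in lambda
  for (rep in 1:5) {
    Sr <- sample_covariance(matrix(rnorm(60 * 10), 60))
    lams <- sort(runif(4, 0.02, 0.6))
    dens <- vapply(lams, function(l)
      graphical_lasso(Sr, l)$density, numeric(1))
    expect_true(all(diff(dens) <= 1e-12))
  }
})

test_that("adjacency series carry partial-correlation weights at matched densities", {
  spec <- make_sparse_precision(15, 0.12, n_hubs = 2, seed = 6)
  x <- sample_suvr_matrix(spec, 300, seed = 7)
  ser <- build_adjacency_series(x, densities = c(0.10, 0.15, 0.20))
  expect_s3_class(ser, "adjacency_series")
  for (i in 1:3) {
    A <- ser$adjacency[[i]]
    W <- ser$weights[[i]]
    expect_lt(abs(ser$realized_densities[i] - ser$densities[i]), 0.011)
    expect_true(all(diag(A) == 0))
    expect_identical(A, t(A))
    # weights nonzero exactly on retained edges
    expect_true(all((W != 0) == (A == 1)))
  }

  # partial correlation sign: negative precision entry, positive weight
  f <- graphical_lasso(sample_covariance(x), 0.05)
  pc <- partial_correlation(f$theta)
  off <- upper.tri(f$theta)
  nz <- off & f$theta != 0
  expect_true(all(sign(pc[nz]) == -sign(f$theta[nz])))

  # identity-precision data: estimated graphs empty at moderate penalty
  id <- make_sparse_precision(10, 0, seed = 8)
  xi <- sample_suvr_matrix(id, 500, seed = 9)
  fi <- graphical_lasso(sample_covariance(xi), 0.3)
  expect_equal(fi$density, 0)

  # permutation equivariance: relabeling ROIs permutes everything in step
  # (up to the solver tolerance: the coordinate-descent path visits
  # columns in index order)
  perm <- sample(ncol(x$values))
  f1 <- graphical_lasso(sample_covariance(x$values), 0.1, tol = 1e-7)
  f2 <- graphical_lasso(sample_covariance(x$values[, perm]), 0.1, tol = 1e-7)
  expect_equal(unname(f2$theta), unname(f1$theta[perm, perm]),
               tolerance = 1e-4)
})

test_that("bootstrap edge differences are calibrated and reproducible", {
  spec <- make_sparse_precision(10, 0.15, n_hubs = 2, seed = 10)
  x <- sample_suvr_matrix(spec, 60, seed = 11)

  # same data in both groups: few spurious CI exclusions
  bt <- bootstrap_edges(x, x, density = 0.15, B = 200, seed = 12)
  expect_lte(mean(bt$label != "ns"), 0.07)

  bt2 <- bootstrap_edges(x, x, density = 0.15, B = 200, seed = 12)
  expect_identical(bt, bt2)

  expect_error(bootstrap_edges(x$values[1:2, ], x$values, B = 200), "3 subjects")
  expect_error(bootstrap_edges(x, x, B = 50), "B must be")
})

test_that("a planted strengthened edge is flagged as enhanced", {
  # two groups identical except one edge's partial correlation raised
  # shrinkage of the penalized weights limits per-seed power (see the
  # methods write-up): assert detection in a clear majority of seeds and
  # the correct direction in nearly all
  hits <- 0
  obs <- numeric(10)
  for (s in 1:10) {
    fx <- strengthened_edge_pair(seed = 20 + s)
    xa <- sample_suvr_matrix(fx$strong, 100, "a", seed = 300 + s)
    xb <- sample_suvr_matrix(fx$base, 100, "b", seed = 400 + s)
    bt <- bootstrap_edges(xa, xb, density = 0.15, B = 150, seed = 500 + s)
    row <- bt[bt$roi_i == "roi007" & bt$roi_j == "roi008", ]
    hits <- hits + (row$label == "enhanced")
    obs[s] <- row$observed
  }
  expect_gte(hits, 6)
  expect_gte(sum(obs > 0), 9)  # the difference points the planted way
})
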