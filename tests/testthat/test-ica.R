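vol_matrix <- function(ds) {
  t(vapply(ds$volumes, function(v) as.vector(v$data),
           numeric(prod(dim(ds$volumes[[1]]$data)))))
}

test_that("component-count estimation tracks the true signal rank", {
  # noiseless rank-2 data: the spectrum is exactly rank 2
  set.seed(1)
  A <- matrix(rnorm(20 * 2), 20)
  S <- matrix(rexp(2 * 500), 2)
  expect_equal(estimate_n_components(A %*% S), 2L)

  ds <- make_volume_dataset(n_subjects = 30, n_sources = 3, noise_sd = 0.1,
                            seed = 2)
  expect_equal(estimate_n_components(vol_matrix(ds)), 3L)

  # iid noise: no structured components
  set.seed(3)
  expect_lte(estimate_n_components(matrix(rnorm(30 * 1500), 30)), 2L)

  expect_error(estimate_n_components(matrix(rnorm(4), 2, 2)), "3 subjects")
  expect_error(estimate_n_components(matrix(0, 5, 100)), "zero variance")
})

test_that("PCA whitening yields identity covariance and round-trips", {
  set.seed(4)
  X <- matrix(rnorm(12 * 300), 12)
  wh <- pca_whiten(X, 5)
  expect_equal(wh$y %*% t(wh$y) / ncol(X), diag(5), tolerance = 1e-8)

  # dewhitening reconstructs the rank-k PCA approximation (SVD oracle)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  Xk <- sv$u[, 1:5] %*% diag(sv$d[1:5]) %*% t(sv$v[, 1:5])
  expect_lt(max(abs(wh$dewhitening %*% wh$y - Xk)), 1e-8)

  # full-rank whitening reconstructs the data exactly
  whf <- pca_whiten(X, 12)
  expect_lt(max(abs(whf$dewhitening %*% whf$y - Xc)), 1e-8)

  expect_error(pca_whiten(X, 13), "rank bound")
})

test_that("Infomax separates planted super-Gaussian spatial sources", {
  ds0 <- make_volume_dataset(n_subjects = 20, n_sources = 2, noise_sd = 0,
                             seed = 5)
  X0 <- vol_matrix(ds0)
  ica0 <- infomax_ica(pca_whiten(X0, 2), seed = 6)
  for (tr in 1:2)
    expect_gte(max(abs(cor(ds0$maps[tr, ], t(ica0$maps)))), 0.99)
  expect_true(ica0$converged)

  # whitened rank-k data are reconstructed by mixing %*% maps
  Xc <- X0 - rowMeans(X0)
  expect_lt(max(abs(ica0$mixing %*% ica0$maps - Xc)), 1e-6)

  # z-maps are unit-scaled
  expect_equal(rowMeans(ica0$z_maps), c(0, 0), tolerance = 1e-6)
  expect_equal(apply(ica0$z_maps, 1, sd), c(1, 1), tolerance = 1e-6)

  # same seed gives a bit-identical result
  ica0b <- infomax_ica(pca_whiten(X0, 2), seed = 6)
  expect_identical(ica0$maps, ica0b$maps)
  expect_identical(ica0$mixing, ica0b$mixing)

  # sign convention: each map's peak-magnitude voxel is positive
  for (c_i in 1:2)
    expect_gt(ica0$maps[c_i, which.max(abs(ica0$maps[c_i, ]))], 0)
})

test_that("z thresholding is strict, positive-tailed, and nested", {
  expect_identical(threshold_z(c(1.0, 2.0, 2.5)), c(FALSE, TRUE, TRUE))
  expect_false(any(threshold_z(c(-3, -2, -0.1))))
  expect_true(all(threshold_z(c(-3, 0, 3), z_cut = -Inf)))
  expect_identical(threshold_z(c(-3, 0, 3), two_tailed = TRUE),
                   c(TRUE, FALSE, TRUE))
  set.seed(7)
  z <- rnorm(200)
  m1 <- threshold_z(z, 1.0)
  m2 <- threshold_z(z, 2.0)
  expect_true(all(m1 | !m2))  # lower cut contains higher cut
})

test_that("template matching assigns components greedily with index tie-breaks", {
  # a component equal to a z-scored template mask matches it perfectly
  set.seed(8)
  tmpl <- list(DMN = c(rep(TRUE, 20), rep(FALSE, 80)),
               SN = c(rep(FALSE, 80), rep(TRUE, 20)))
  z1 <- scale(as.numeric(tmpl$DMN))[, 1]
  z2 <- scale(as.numeric(tmpl$SN))[, 1]
  z3 <- rnorm(100)
  zm <- rbind(z3, z1, z2)
  asg <- match_templates(zm, tmpl)
  expect_equal(asg$component[asg$template == "DMN"], 2)
  expect_equal(asg$component[asg$template == "SN"], 3)
  expect_equal(asg$correlation[asg$template == "DMN"], 1, tolerance = 1e-12)

  # identical components: the lowest index wins
  zm2 <- rbind(z1, z1)
  asg2 <- match_templates(zm2, tmpl["DMN"])
  expect_equal(asg2$component, 1)

  # recovered blob components match their own generating templates
  ds <- make_volume_dataset(n_subjects = 25, n_sources = 3, noise_sd = 0.05,
                            seed = 9)
  ica <- infomax_ica(pca_whiten(vol_matrix(ds), 3), seed = 10)
  asg3 <- match_templates(ica, ds$templates)
  truth_best <- vapply(seq_len(3), function(t_i)
    which.max(abs(cor(ds$maps[t_i, ], t(ica$maps)))), integer(1))
  expect_identical(asg3$component[match(names(ds$templates), asg3$template)],
                   truth_best)
  expect_true(all(asg3$correlation > 0.5))

  expect_error(match_templates(zm2, c(tmpl, tmpl["DMN"])), "more templates")
})

test_that("within-network comparison is calibrated and detects planted change", {
  spec <- make_sparse_precision(8, 0.2, n_hubs = 0, seed = 11)
  xa <- sample_suvr_matrix(spec, 40, "a", seed = 12)
  xb <- sample_suvr_matrix(spec, 40, "b", seed = 13)

  # same generating model in both groups: few flagged edges
  cmp <- compare_network(xa, xb, density = 0.2, n_perm = 200, seed = 14)
  expect_lte(mean(cmp$edges$label != "ns"), 0.1)
  expect_false(any(cmp$nodes$flag))

  cmp2 <- compare_network(xa, xb, density = 0.2, n_perm = 200, seed = 14)
  expect_identical(cmp$edges, cmp2$edges)

  # planted strengthening in one group: flagged as increased in a
  # plurality of seeds and directionally consistent almost always (the
  # permutation null for weight differences is wide; see methods)
  hits <- 0
  obs <- numeric(10)
  for (s in 1:10) {
    fx <- strengthened_edge_pair(seed = 20 + s)
    xs <- sample_suvr_matrix(fx$strong, 100, "a", seed = 120 + s)
    xw <- sample_suvr_matrix(fx$base, 100, "b", seed = 220 + s)
    cmp3 <- compare_network(xs, xw, density = 0.15, n_perm = 200,
                            seed = 320 + s)
    row <- cmp3$edges[cmp3$edges$roi_i == "roi007" &
                        cmp3$edges$roi_j == "roi008", ]
    hits <- hits + (row$label == "increased")
    obs[s] <- row$observed
  }
  expect_gte(hits, 4)
  expect_gte(sum(obs > 0), 9)

  expect_error(compare_network(subset_rois(xa, 1:2), subset_rois(xb, 1:2)),
               "3 ROIs")
})
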