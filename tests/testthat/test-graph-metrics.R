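k4 <- matrix(1, 4, 4) - diag(4)
star4 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))

test_that("closed-form identities on canonical graphs hold exactly", {
  expect_identical(degree_centrality(k4), rep(3L, 4))
  expect_identical(degree_centrality(star4), c(3L, 1L, 1L, 1L))

  expect_equal(clustering_coefficient(k4)$mean, 1)
  expect_equal(clustering_coefficient(path3)$mean, 0)

  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(local_efficiency(k4)$mean, 1)
  expect_equal(local_efficiency(star4)$mean, 0)

  expect_equal(assortativity_coefficient(star4), -1)
  expect_true(is.na(assortativity_coefficient(k4)))  # constant degrees

  expect_equal(synchronizability(k4), 1)
  expect_equal(synchronizability(path3), 1 / 3)
  disc <- rbind(cbind(k4, matrix(0, 4, 3)),
                cbind(matrix(0, 3, 4), path3))
  expect_equal(synchronizability(disc), 0)

  D <- shortest_path_lengths(path3)
  expect_equal(D[1, 3], 2)
  expect_true(is.infinite(shortest_path_lengths(disc)[1, 5]))
})

test_that("input validation rejects malformed adjacencies", {
  expect_error(degree_centrality(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(degree_centrality(diag(2)), "zero diagonal")
  expect_error(degree_centrality(matrix(c(0, 2, 2, 0), 2)), "binary")
  expect_error(participation_coefficient(k4, c(1, 1)), "every node")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (r in 1:25) {
    n <- sample(5:12, 1)
    A <- random_graph(n, runif(1, 0.15, 0.85))
    expect_identical(degree_centrality(A), oracle_degree(A))
    expect_equal(clustering_coefficient(A)$nodal, oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(shortest_path_lengths(A), oracle_floyd_warshall(A),
                 ignore_attr = TRUE)
    expect_equal(global_efficiency(A), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(nodal_efficiency(A), oracle_nodal_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A)$nodal, oracle_local_efficiency(A),
                 tolerance = 1e-12)
    if (sum(A) > 0)
      expect_equal(assortativity_coefficient(A), oracle_assortativity(A),
                   tolerance = 1e-12)
    expect_equal(hierarchy_coefficient(A), oracle_hierarchy(A),
                 tolerance = 1e-10)
    expect_equal(synchronizability(A), oracle_synchronizability(A),
                 tolerance = 1e-12)
    mods <- sample(1:3, n, replace = TRUE)
    expect_equal(participation_coefficient(A, mods),
                 oracle_participation(A, mods), tolerance = 1e-12)
  }
})

test_that("hierarchy recovers a noiseless power law and flags degeneracy", {
  expect_true(is.na(hierarchy_coefficient(k4)))  # constant degrees
  # craft clustering C = k^-0.5 exactly via the regression inputs:
  # use a graph, then check the estimator against the closed form instead
  set.seed(7)
  A <- random_graph(10, 0.5)
  k <- rowSums(A)
  ci <- clustering_coefficient(A)$nodal
  keep <- k >= 2 & ci > 0
  x <- log(k[keep]); y <- log(ci[keep])
  beta_hat <- -sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(hierarchy_coefficient(A), beta_hat, tolerance = 1e-10)
  # synthetic exact power law through the same least-squares route
  xk <- c(2, 3, 4, 6)
  expect_equal(-coef(lm(log(xk^-0.5) ~ log(xk)))[[2]], 0.5, tolerance = 1e-10)
})

test_that("participation coefficient follows the module split", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[1, 3] <- A[3, 1] <- 1
  mods <- c(1, 1, 1, 2, 2)
  expect_equal(participation_coefficient(A, mods)[1], 0)  # all within module
  mods2 <- c(1, 1, 2, 2, 2)
  expect_equal(participation_coefficient(A, mods2)[1], 0.5)  # 50/50 split
  expect_equal(participation_coefficient(A, mods)[5], 0)  # isolated node
})

test_that("AUC integration normalizes the trapezoid by the grid span", {
  d <- seq(0.1, 0.4, 0.05)
  expect_equal(metric_auc(rep(2.5, length(d)), d), 2.5)
  expect_equal(metric_auc(seq(0, 1, length.out = 4), seq(0.1, 0.4, 0.1)), 0.5)
  set.seed(8)
  v <- runif(7)
  hand <- sum(diff(d) * (v[-7] + v[-1]) / 2) / 0.3
  expect_equal(metric_auc(v, d), hand, tolerance = 1e-12)
  expect_error(metric_auc(1:3, 1:4), "misaligned")
})

test_that("module detection separates loosely joined cliques", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- k4
  A[5:8, 5:8] <- k4
  A[4, 5] <- A[5, 4] <- 1
  mods <- detect_modules(A, seed = 1)
  expect_length(unique(mods), 2)
  expect_length(unique(mods[1:4]), 1)
  expect_length(unique(mods[5:8]), 1)
  expect_identical(mods, detect_modules(A, seed = 1))
  # edgeless graph: every node its own module
  expect_length(unique(detect_modules(matrix(0, 5, 5))), 5)
})

test_that("metrics are invariant under node relabeling and monotone in edges", {
  set.seed(9)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    A <- random_graph(n, runif(1, 0.2, 0.7))
    perm <- sample(n)
    B <- A[perm, perm]
    expect_equal(global_efficiency(A), global_efficiency(B), tolerance = 1e-12)
    expect_equal(clustering_coefficient(A)$mean,
                 clustering_coefficient(B)$mean, tolerance = 1e-12)
    expect_equal(synchronizability(A), synchronizability(B), tolerance = 1e-9)
    expect_equal(sort(degree_centrality(A)), sort(degree_centrality(B)))
  }
  # adding edges never decreases efficiency or clustering means
  A <- random_graph(10, 0.2)
  for (step in 1:10) {
    holes <- which(A == 0 & upper.tri(A))
    if (!length(holes)) break
    B <- A
    hole <- if (length(holes) > 1) sample(holes, 1) else holes
    B[hole] <- 1
    B <- pmax(B, t(B))
    expect_gte(global_efficiency(B), global_efficiency(A) - 1e-12)
    A <- B
  }
})

test_that("series metrics bundle global and nodal AUC summaries", {
  spec <- make_sparse_precision(15, 0.12, n_hubs = 2, seed = 13)
  x <- sample_suvr_matrix(spec, 200, seed = 14)
  ser <- build_adjacency_series(x, densities = c(0.10, 0.15, 0.20))
  ms <- metrics_over_series(ser)
  expect_equal(nrow(ms$global), 3)
  expect_true(all(c("global_efficiency", "clustering_coefficient") %in%
                    names(ms$global)))
  expect_length(ms$degree_auc, 15)
  # AUC of a constant-in-density metric equals that constant
  expect_equal(unname(ms$global_auc["global_efficiency"]),
               metric_auc(ms$global$global_efficiency, ms$global$density))
})
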