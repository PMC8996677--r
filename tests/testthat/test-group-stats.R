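test_that("permutation test preserves group sizes and handles degenerate data", {
  # constant data: zero observed difference, p = 1 under the >= convention
  Xa <- matrix(1, 5, 3)
  Xb <- matrix(1, 7, 3)
  mean_stat <- function(A, B) mean(A[, 1]) - mean(B[, 1])
  pt <- permutation_test(Xa, Xb, mean_stat, n_perm = 100, seed = 1)
  expect_equal(pt$observed, 0)
  expect_equal(pt$p_value, 1)

  # obvious shift on a transparent statistic: tiny p
  set.seed(2)
  Xa <- matrix(rnorm(50 * 4), 50); Xa[, 1] <- Xa[, 1] + 5
  Xb <- matrix(rnorm(50 * 4), 50)
  pt2 <- permutation_test(Xa, Xb, mean_stat, n_perm = 500, seed = 3)
  expect_lte(pt2$p_value, 0.01)

  # the (b+1)/(B+1) correction keeps p strictly positive
  pt3 <- permutation_test(Xa, Xb, mean_stat, n_perm = 200, seed = 3,
                          correction = TRUE)
  expect_gt(pt3$p_value, 0)

  # fixed seed reproduces the whole permutation distribution
  pt4 <- permutation_test(Xa, Xb, mean_stat, n_perm = 200, seed = 9)
  pt5 <- permutation_test(Xa, Xb, mean_stat, n_perm = 200, seed = 9)
  expect_identical(pt4$perms, pt5$perms)

  expect_error(permutation_test(Xa, Xb, mean_stat, n_perm = 50), "n_perm")
})

test_that("exhaustive enumeration gives the exact permutation p-value", {
  set.seed(4)
  Xa <- matrix(rnorm(3 * 2), 3)
  Xb <- matrix(rnorm(3 * 2), 3)
  stat <- function(A, B) mean(A) - mean(B)
  ex <- exact_permutation_test(Xa, Xb, stat)
  expect_equal(ex$n_perm, choose(6, 3))  # all 20 assignments

  # zero observed difference on symmetric data: exact p = 1
  Xs <- matrix(rnorm(8), 4)
  exs <- exact_permutation_test(Xs, Xs, stat)
  expect_equal(exs$observed, 0)
  expect_equal(exs$p_value, 1)

  # Monte-Carlo agrees with enumeration within 3 binomial SEs
  for (s in 1:5) {
    set.seed(100 + s)
    Xa <- matrix(rnorm(4 * 2, mean = 0.5), 4)
    Xb <- matrix(rnorm(5 * 2), 5)
    ex <- exact_permutation_test(Xa, Xb, stat)
    mc <- permutation_test(Xa, Xb, stat, n_perm = 2000, seed = 200 + s)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 2000)
    expect_lte(abs(mc$p_value - ex$p_value), max(3 * se, 0.01))
  }

  big <- matrix(rnorm(40), 20)
  expect_error(exact_permutation_test(big, big, stat), "enumerate")
})

test_that("GLM contrast reduces to the two-sample t and adjusts for covariates", {
  set.seed(5)
  y <- c(rnorm(12, 0), rnorm(10, 1))
  g <- rep(c("ctrl", "pat"), c(12, 10))
  res <- glm_contrast(y, g)
  tt <- t.test(y[g == "pat"], y[g == "ctrl"], var.equal = TRUE)
  expect_equal(abs(res$t), abs(tt$statistic[[1]]), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)

  # response equal to a covariate: group effect vanishes
  age <- rnorm(22, 50, 8)
  res2 <- glm_contrast(age, g, data.frame(age = age))
  expect_lt(abs(res2$beta), 1e-10)

  # affine rescaling of covariates leaves the group effect untouched
  cov1 <- data.frame(age = age, sex = rep(0:1, 11))
  cov2 <- data.frame(age = 10 * age - 300, sex = rep(0:1, 11))
  r1 <- glm_contrast(y, g, cov1)
  r2 <- glm_contrast(y, g, cov2)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)

  # standardized beta recovers a planted effect size
  betas <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    gg <- rep(0:1, each = 100)
    yy <- 0.9 * gg + rnorm(200)
    glm_contrast(yy, factor(gg))$beta
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.9 / sqrt(0.9^2 / 4 + 1)), 0.15)

  expect_error(glm_contrast(y, g, data.frame(dup = as.numeric(g == "pat"))),
               "rank deficient")
  expect_error(glm_contrast(y, rep("a", 22)), "two levels")
})

test_that("effect-size filter uses strict magnitude thresholding", {
  expect_identical(effect_size_filter(c(0.79, 0.80, 0.81)),
                   c(FALSE, FALSE, TRUE))
  expect_true(effect_size_filter(-0.9))
  expect_identical(effect_size_filter(c(-0.5, 0, 0.5), threshold = 0),
                   c(TRUE, FALSE, TRUE))
  expect_error(effect_size_filter(c(1, Inf)), "finite")
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, TRUE, FALSE))

  r1 <- fdr_bh(rep(1, 6))
  expect_false(any(r1$reject))
  expect_true(all(r1$p_adjusted == 1))

  # explicit sort/scan oracle on random p-vectors
  set.seed(6)
  for (rep in 1:20) {
    m <- sample(3:50, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- fdr_bh(p)$p_adjusted
    o <- order(p)
    scaled <- p[o] * m / seq_len(m)
    adj_o <- rev(cummin(rev(pmin(scaled, 1))))
    expect_equal(adj[o], adj_o, tolerance = 1e-12)
  }

  # rejections grow monotonically with q
  p <- runif(40)^2
  rej1 <- fdr_bh(p, 0.02)$reject
  rej2 <- fdr_bh(p, 0.10)$reject
  expect_true(all(rej2 | !rej1))

  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")
})

test_that("network-statistic permutation test runs the full SICE chain", {
  spec <- make_sparse_precision(12, 0.15, n_hubs = 2, seed = 7)
  xa <- sample_suvr_matrix(spec, 15, "a", seed = 8)
  xb <- sample_suvr_matrix(spec, 20, "b", seed = 9)
  pt <- permutation_test(xa, xb, network_statistic("global_efficiency", 0.2),
                         n_perm = 200, seed = 10)
  expect_gte(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_length(pt$perms, 200)
  pt2 <- permutation_test(xa, xb, network_statistic("global_efficiency", 0.2),
                          n_perm = 200, seed = 10)
  expect_identical(pt$perms, pt2$perms)
  # observed difference agrees with the R-path evaluation of the same chain
  stat <- network_statistic("global_efficiency", 0.2)
  obs_r <- metconn:::eval_network_statistic(stat, xa$values) -
    metconn:::eval_network_statistic(stat, xb$values)
  expect_equal(pt$observed, obs_r, tolerance = 1e-8)
})
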