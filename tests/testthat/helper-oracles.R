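# Brute-force reference implementations of the graph measures, written
# independently of the package code paths, plus small fixture helpers.

random_graph <- function(n, density) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  m <- round(density * length(ut))
  if (m > 0) {
    sel <- sample(ut, m)
    A[sel] <- 1
  }
  A + t(A)
}

oracle_degree <- function(A) {
  n <- nrow(A)
  k <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (j != i && A[i, j] == 1)
    k[i] <- k[i] + 1L
  k
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) if (a < b &&
        A[nb[a], nb[b]] == 1) t <- t + 1
    ci[i] <- 2 * t / (k * (k - 1))
  }
  ci
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_global_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (nrow(A) * (nrow(A) - 1))
}

oracle_nodal_efficiency <- function(A) {
  D <- oracle_floyd_warshall(A)
  inv <- 1 / D
  diag(inv) <- 0
  rowSums(inv) / (nrow(A) - 1)
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

oracle_assortativity <- function(A) {
  e <- which(A == 1, arr.ind = TRUE)  # both orientations
  k <- oracle_degree(A)
  x <- k[e[, 1]]
  y <- k[e[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

oracle_hierarchy <- function(A) {
  k <- oracle_degree(A)
  ci <- oracle_clustering(A)
  keep <- k >= 2 & ci > 0
  if (sum(keep) < 2 || length(unique(k[keep])) < 2) return(NA_real_)
  x <- log(k[keep])
  y <- log(ci[keep])
  # closed-form simple regression slope
  -(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
}

oracle_synchronizability <- function(A) {
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (ev[length(ev)] <= 1e-12) return(0)
  if (ev[2] < 1e-10) return(0)
  ev[2] / ev[length(ev)]
}

oracle_participation <- function(A, modules) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    if (ki == 0) return(0)
    s <- 0
    for (m in unique(modules)) {
      kim <- sum(A[i, modules == m])
      s <- s + (kim / ki)^2
    }
    1 - s
  }, numeric(1))
}

support_f1 <- function(A_est, A_true) {
  ut <- upper.tri(A_est)
  tp <- sum(A_est[ut] == 1 & A_true[ut] == 1)
  fp <- sum(A_est[ut] == 1 & A_true[ut] == 0)
  fn <- sum(A_est[ut] == 0 & A_true[ut] == 1)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# 2x2 penalized-likelihood maximizer by direct numerical optimization,
# independent of the coordinate-descent solver
oracle_glasso_2x2 <- function(S, lambda) {
  obj <- function(par) {
    theta <- matrix(c(par[1], par[3], par[3], par[2]), 2)
    det_t <- par[1] * par[2] - par[3]^2
    if (par[1] <= 0 || par[2] <= 0 || det_t <= 1e-12) return(1e10)
    -(log(det_t) - sum(S * theta) - lambda * 2 * abs(par[3]))
  }
  par <- c(1, 1, 0)
  for (restart in 1:4)
    par <- optim(par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 10000))$par
  matrix(c(par[1], par[3], par[3], par[2]), 2)
}

grid_volume <- function(dims = c(12, 12, 8), value = 1, spacing = c(2, 2, 2)) {
  volume(array(value, dims), spacing)
}

# Paired-node fixture for edge-difference power checks: disjoint node
# pairs with moderate partial correlations, plus one target pair whose
# positive partial correlation is deepened in the "strong" copy. The
# isolated-pair design keeps the precision well conditioned and the
# planted contrast free of interference from indirect paths.
strengthened_edge_pair <- function(seed, v_base = 0.45, v_strong = 0.8,
                                   p = 8) {
  set.seed(seed)
  th <- diag(p)
  for (e in list(c(1, 2), c(3, 4), c(5, 6))) {
    val <- sample(c(-1, 1), 1) * runif(1, 0.35, 0.45)
    th[e[1], e[2]] <- th[e[2], e[1]] <- val
  }
  th[7, 8] <- th[8, 7] <- -v_base
  th_s <- th
  th_s[7, 8] <- th_s[8, 7] <- -v_strong
  rois <- sprintf("roi%03d", seq_len(p))
  mkspec <- function(theta) {
    dimnames(theta) <- list(rois, rois)
    structure(list(p = p, theta = theta,
                   support = which(upper.tri(theta) & theta != 0,
                                   arr.ind = TRUE),
                   hub_nodes = integer(0), hub_degree = 0L,
                   density = NA, seed = seed),
              class = "precision_spec")
  }
  list(base = mkspec(th), strong = mkspec(th_s), i = 7L, j = 8L)
}
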