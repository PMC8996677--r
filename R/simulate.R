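# Assemble a precision matrix from an edge list with raw values: unit
# diagonal, off-diagonal = values / scale, inflated to min_eig if needed
# (inflation preserves the support exactly).
.theta_from_edges <- function(p, support, values, scale, min_eig = 0.1) {
  theta <- diag(p)
  if (nrow(support)) {
    v <- values / scale
    theta[support] <- v
    theta[support[, c(2, 1), drop = FALSE]] <- v
  }
  ev_min <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < min_eig) diag(theta) <- diag(theta) + (min_eig - ev_min)
  rois <- sprintf("roi%03d", seq_len(p))
  dimnames(theta) <- list(rois, rois)
  theta
}

# Row-norm based scale: largest L2 norm over rows of the raw value matrix,
# padded by 10%, so the unit-diagonal precision stays well conditioned and
# the planted partial correlations keep a usable magnitude.
.edge_scale <- function(p, support, values) {
  Vm <- matrix(0, p, p)
  Vm[support] <- values
  Vm[support[, c(2, 1), drop = FALSE]] <- values
  max(1.1 * sqrt(max(rowSums(Vm^2))), 1)
}

#' Sparse precision matrix with planted hub nodes
#'
#' Generates a ground-truth Gaussian graphical model: a symmetric positive
#' definite precision matrix whose off-diagonal support contains a chosen
#' number of hub nodes of much higher degree (about half the network, and
#' always several times the median non-hub degree). Hub-incident edges
#' carry coherent positive partial correlations — metabolic covariance
#' around real PET hubs is predominantly positive — while background edges
#' alternate in sign. Raw magnitudes from `value_range` are divided by a
#' common row-norm scale so the unit-diagonal precision is well
#' conditioned; a diagonal inflation to `min_eig` is the (rarely needed)
#' fallback and preserves the planted support exactly.
#'
#' @param p number of ROIs (>= 4).
#' @param density requested off-diagonal edge density in [0, 1).
#' @param n_hubs number of planted hub nodes.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @param value_range magnitude range of the raw off-diagonal entries
#'   before scaling.
#' @param min_eig smallest admissible eigenvalue of the precision.
#' @return An object of class `precision_spec`: `p`, `theta`, `support`
#'   (2-column matrix of i < j index pairs), `values` (raw edge values
#'   aligned with `support`), `scale`, `hub_nodes`, `hub_degree`,
#'   `density` (realized), `seed`.
#' @export
make_sparse_precision <- function(p, density, n_hubs = 0, seed = 1L,
                                  value_range = c(0.3, 0.6), min_eig = 0.1) {
  if (p < 4) stop("p must be >= 4")
  if (density < 0 || density >= 1) stop("density must be in [0, 1)")
  .seed_guard(seed)
  n_pairs <- p * (p - 1) / 2
  m_total <- round(density * n_pairs)
  if (n_hubs > 0 && m_total < 3 * n_hubs)
    stop("density too low to plant ", n_hubs, " hubs")
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  edge_id <- function(i, j) {
    ii <- pmin(i, j); jj <- pmax(i, j)
    (jj - 1) * (jj - 2) / 2 + ii
  }
  hub_nodes <- integer(0)
  h <- 0L
  if (m_total == 0) {
    sel <- integer(0)
  } else if (n_hubs == 0) {
    sel <- sample.int(n_pairs, m_total)
  } else {
    hub_nodes <- sort(sample.int(p, n_hubs))
    h <- max(3L, min(as.integer(round(0.55 * p)), m_total %/% n_hubs))
    sel <- integer(0)
    for (hub in hub_nodes) {
      partners <- sample(setdiff(seq_len(p), hub), h)
      sel <- c(sel, edge_id(rep(hub, h), partners))
    }
    sel <- unique(sel)
    m_bg <- m_total - length(sel)
    if (m_bg > 0) {
      nonhub <- setdiff(seq_len(p), hub_nodes)
      bg_ok <- pairs[, 1] %in% nonhub & pairs[, 2] %in% nonhub
      bg_pool <- setdiff(which(bg_ok), sel)
      if (length(bg_pool) < m_bg) bg_pool <- setdiff(seq_len(n_pairs), sel)
      sel <- c(sel, sample(bg_pool, m_bg))
    }
  }
  realized <- length(sel) / n_pairs
  if (m_total > 0 && abs(realized - density) / density > 0.1)
    stop("could not realize requested density within 10%")
  support <- pairs[sel, , drop = FALSE]
  colnames(support) <- c("i", "j")
  values <- numeric(0)
  scale <- 1
  if (nrow(support)) {
    sgn <- sample(c(-1, 1), nrow(support), replace = TRUE)
    if (length(hub_nodes)) {
      hub_edge <- support[, 1] %in% hub_nodes | support[, 2] %in% hub_nodes
      sgn[hub_edge] <- -1  # negative precision entry = positive partial corr
    }
    values <- runif(nrow(support), value_range[1], value_range[2]) * sgn
    scale <- .edge_scale(p, support, values)
  }
  theta <- .theta_from_edges(p, support, values, scale, min_eig)
  ord <- order(support[, 1], support[, 2])
  structure(list(p = p, theta = theta,
                 support = support[ord, , drop = FALSE],
                 values = values[ord], scale = scale,
                 hub_nodes = hub_nodes, hub_degree = h,
                 density = realized, seed = seed),
            class = "precision_spec")
}

#' @export
print.precision_spec <- function(x, ...) {
  cat(sprintf("<precision_spec> p=%d, %d edges (density %.3f), hubs: %s\n",
              x$p, nrow(x$support), x$density,
              if (length(x$hub_nodes)) paste(x$hub_nodes, collapse = ",")
              else "none"))
  invisible(x)
}

#' True node degrees of a precision spec
#'
#' @param spec a [make_sparse_precision()] result.
#' @return Integer vector of degrees of the planted support.
#' @export
true_degrees <- function(spec) {
  stopifnot(inherits(spec, "precision_spec"))
  tabulate(c(spec$support[, 1], spec$support[, 2]), nbins = spec$p)
}

#' Sample an SUVR matrix from a planted precision model
#'
#' Rows are independent draws from the multivariate normal with covariance
#' `solve(theta)`, shifted to a positive SUVR-like mean level (the shift is
#' covariance-invariant). Age (normal) and sex (Bernoulli) covariates are
#' attached for the GLM stage.
#'
#' @param spec a [make_sparse_precision()] result.
#' @param n number of subjects (>= 2).
#' @param group_label group name for all sampled subjects.
#' @param seed integer seed.
#' @param mean_level mean SUVR level added to every ROI.
#' @param age_mean,age_sd,sex_prob covariate distribution parameters.
#' @return A [suvr_matrix()].
#' @export
sample_suvr_matrix <- function(spec, n, group_label = "A", seed = NULL,
                               mean_level = 1.2, age_mean = 50, age_sd = 10,
                               sex_prob = 0.5) {
  stopifnot(inherits(spec, "precision_spec"))
  if (n < 2) stop("n must be >= 2")
  .seed_guard(seed)
  sigma <- solve(spec$theta)
  sigma <- (sigma + t(sigma)) / 2
  X <- MASS::mvrnorm(n, mu = rep(mean_level, spec$p), Sigma = sigma)
  covs <- data.frame(age = rnorm(n, age_mean, age_sd),
                     sex = rbinom(n, 1, sex_prob))
  suvr_matrix(X, rep(group_label, n),
              subject_ids = sprintf("%s%03d", group_label, seq_len(n)),
              roi_labels = colnames(spec$theta), covariates = covs)
}

#' Group pair with planted lost and reconfigured hubs
#'
#' Derives a target-group precision model from a control-like one by (i)
#' stripping planted "lost" hubs down to a floor degree and (ii) raising
#' chosen non-hub nodes to hub degree ("reconfigured") by adding edges.
#' Every edit is logged; both matrices are re-inflated to positive
#' definiteness without touching the edited support.
#'
#' @param p,density,n_hubs,seed as in [make_sparse_precision()].
#' @param edits list with `n_lost`, `n_reconfigured` and `floor_degree`
#'   (residual degree of a lost hub).
#' @return An object of class `group_pair_spec`: `spec_a` (control truth),
#'   `spec_b` (target truth), `planted_lost`, `planted_reconfigured`,
#'   `edit_log` (data.frame action/i/j/value), `seed`.
#' @export
make_group_pair <- function(p, density = 0.1,
                            edits = list(n_lost = 1, n_reconfigured = 1,
                                         floor_degree = 2),
                            n_hubs = 3L,
                            seed = 1L) {
  edits <- modifyList(list(n_lost = 1, n_reconfigured = 1, floor_degree = 2),
                      as.list(edits))
  spec_a <- make_sparse_precision(p, density, n_hubs, seed)
  # continue the seeded RNG stream for the edit draws
  if (edits$n_lost > length(spec_a$hub_nodes))
    stop("cannot lose more hubs than were planted")
  if (edits$n_lost == 0 && edits$n_reconfigured == 0) {
    return(structure(list(spec_a = spec_a, spec_b = spec_a,
                          planted_lost = integer(0),
                          planted_reconfigured = integer(0),
                          edit_log = data.frame(action = character(0),
                                                i = integer(0), j = integer(0),
                                                value = numeric(0)),
                          seed = seed),
                     class = "group_pair_spec"))
  }
  lost <- sort(sample(spec_a$hub_nodes, edits$n_lost))
  nonhub <- setdiff(seq_len(p), spec_a$hub_nodes)
  reconf <- sort(sample(nonhub, edits$n_reconfigured))

  sup <- spec_a$support
  vals <- spec_a$values
  log_rows <- list()
  for (node in lost) {
    inc <- which(sup[, 1] == node | sup[, 2] == node)
    if (length(inc) > edits$floor_degree) {
      drop <- sample(inc, length(inc) - edits$floor_degree)
      for (r in drop)
        log_rows[[length(log_rows) + 1]] <-
          data.frame(action = "remove", i = sup[r, 1], j = sup[r, 2],
                     value = vals[r])
      sup <- sup[-drop, , drop = FALSE]
      vals <- vals[-drop]
    }
  }
  h_target <- max(spec_a$hub_degree, 3L)
  for (node in reconf) {
    connected <- c(sup[sup[, 1] == node, 2], sup[sup[, 2] == node, 1])
    pool <- setdiff(seq_len(p), c(node, connected, lost))
    n_add <- min(h_target - length(connected), length(pool))
    if (n_add > 0) {
      partners <- sample(pool, n_add)
      for (q in partners) {
        i <- min(node, q); j <- max(node, q)
        v <- -runif(1, 0.3, 0.6)  # coherent positive partial correlation
        sup <- rbind(sup, c(i, j))
        vals <- c(vals, v)
        log_rows[[length(log_rows) + 1]] <-
          data.frame(action = "add", i = i, j = j, value = v)
      }
    }
  }
  # common scale so preserved edges keep identical precision entries
  scale <- max(spec_a$scale, .edge_scale(p, sup, vals))
  ord <- order(sup[, 1], sup[, 2])
  sup <- sup[ord, , drop = FALSE]
  vals <- vals[ord]
  colnames(sup) <- c("i", "j")
  spec_a$scale <- scale
  spec_a$theta <- .theta_from_edges(p, spec_a$support, spec_a$values, scale)
  spec_b <- structure(list(p = p,
                           theta = .theta_from_edges(p, sup, vals, scale),
                           support = sup, values = vals, scale = scale,
                           hub_nodes = sort(c(setdiff(spec_a$hub_nodes, lost),
                                              reconf)),
                           hub_degree = h_target,
                           density = nrow(sup) / (p * (p - 1) / 2),
                           seed = seed),
                      class = "precision_spec")
  structure(list(spec_a = spec_a, spec_b = spec_b, planted_lost = lost,
                 planted_reconfigured = reconf,
                 edit_log = do.call(rbind, log_rows), seed = seed),
            class = "group_pair_spec")
}

#' @export
print.group_pair_spec <- function(x, ...) {
  cat(sprintf(
    "<group_pair_spec> p=%d, lost: %s, reconfigured: %s, %d edits\n",
    x$spec_a$p,
    if (length(x$planted_lost)) paste(x$planted_lost, collapse = ",") else "-",
    if (length(x$planted_reconfigured))
      paste(x$planted_reconfigured, collapse = ",") else "-",
    if (is.null(x$edit_log)) 0L else nrow(x$edit_log)))
  invisible(x)
}
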