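#' @name graph_metrics
#' @title Graph-theory measures on binary undirected networks
#'
#' @description Measures of the metabolic network's topology, computed on a
#' binary symmetric adjacency matrix with zero diagonal (as produced by
#' [adjacency_from_precision()]). Global measures: assortativity, hierarchy,
#' mean clustering coefficient, global and local efficiency,
#' synchronizability and characteristic path length. Nodal measures: degree
#' centrality, clustering, mean shortest path length, nodal and local
#' efficiency and participation coefficient. Path-based quantities are
#' computed over reachable pairs only (1/infinity counts as 0 towards
#' efficiencies); measures that are undefined on a given graph (e.g.
#' assortativity with constant degrees) return `NA` rather than 0.
NULL

check_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(A != 0 & A != 1)) stop("adjacency must be binary (0/1)")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal (no self-loops)")
  storage.mode(A) <- "double"
  A
}

#' @rdname graph_metrics
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return `degree_centrality`: integer vector of node degrees.
#' @export
degree_centrality <- function(A) {
  A <- check_adjacency(A)
  as.integer(rowSums(A))
}

#' @rdname graph_metrics
#' @return `clustering_coefficient`: list with per-node `nodal` values
#'   (`2 t_i / (k_i (k_i - 1))`, 0 when `k_i < 2`) and their `mean`.
#' @export
clustering_coefficient <- function(A) {
  A <- check_adjacency(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  list(nodal = as.numeric(ci), mean = mean(ci))
}

#' @rdname graph_metrics
#' @return `shortest_path_lengths`: matrix of pairwise hop counts (`Inf`
#'   for unreachable pairs, 0 diagonal), by breadth-first search.
#' @export
shortest_path_lengths <- function(A) {
  A <- check_adjacency(A)
  D <- cpp_shortest_paths(A)
  dimnames(D) <- dimnames(A)
  D
}

#' @rdname graph_metrics
#' @return `global_efficiency`: mean of `1/d(i,j)` over ordered pairs
#'   (`1/Inf = 0`).
#' @export
global_efficiency <- function(A) {
  A <- check_adjacency(A)
  if (nrow(A) < 2) stop("need at least 2 nodes")
  cpp_bin_metric(A, 1L)
}

#' @rdname graph_metrics
#' @return `nodal_efficiency`: per-node mean of `1/d(i,j)` over the other
#'   nodes.
#' @export
nodal_efficiency <- function(A) {
  A <- check_adjacency(A)
  if (nrow(A) < 2) stop("need at least 2 nodes")
  D <- cpp_shortest_paths(A)
  inv <- 1 / D
  diag(inv) <- 0
  as.numeric(rowSums(inv) / (nrow(A) - 1))
}

#' @rdname graph_metrics
#' @return `local_efficiency`: list with per-node `nodal` values (global
#'   efficiency of the subgraph induced by each node's neighbors; 0 when
#'   degree < 2) and their `mean`.
#' @export
local_efficiency <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  el <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    cpp_bin_metric(A[nb, nb, drop = FALSE], 1L)
  }, numeric(1))
  list(nodal = el, mean = mean(el))
}

#' @rdname graph_metrics
#' @return `characteristic_path_length`: list with `L` (mean shortest path
#'   over reachable ordered pairs) and `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(A) {
  A <- check_adjacency(A)
  D <- cpp_shortest_paths(A)
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  list(L = if (any(reach)) mean(off[reach]) else NA_real_,
       n_unreachable_pairs = sum(!reach))
}

#' @rdname graph_metrics
#' @return `assortativity_coefficient`: Pearson correlation of degrees over
#'   edge endpoints (both orientations); `NA` when degenerate (no edges or
#'   zero degree variance at the endpoints).
#' @export
assortativity_coefficient <- function(A) {
  A <- check_adjacency(A)
  k <- rowSums(A)
  e <- which(A != 0, arr.ind = TRUE)  # both orientations
  if (nrow(e) == 0) stop("assortativity needs at least one edge")
  x <- k[e[, 1]]
  y <- k[e[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' @rdname graph_metrics
#' @return `hierarchy_coefficient`: exponent `beta` of `C(k) ~ k^-beta`,
#'   the negated slope of the least-squares fit of `log C_i` on `log k_i`
#'   over nodes with `k_i >= 2` and `C_i > 0`; `NA` when fewer than two
#'   such nodes with distinct degrees exist.
#' @export
hierarchy_coefficient <- function(A) {
  A <- check_adjacency(A)
  k <- rowSums(A)
  ci <- clustering_coefficient(A)$nodal
  keep <- k >= 2 & ci > 0
  if (sum(keep) < 2 || length(unique(k[keep])) < 2) return(NA_real_)
  fit <- lm(log(ci[keep]) ~ log(k[keep]))
  -unname(coef(fit)[2])
}

#' @rdname graph_metrics
#' @return `synchronizability`: ratio of the second-smallest to the largest
#'   eigenvalue of the combinatorial Laplacian `D - A`; 0 for disconnected
#'   graphs.
#' @export
synchronizability <- function(A) {
  A <- check_adjacency(A)
  if (nrow(A) < 2) stop("need at least 2 nodes")
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- ev[length(ev)]
  if (lmax <= 1e-12) return(0)       # edgeless
  l2 <- ev[2]
  if (l2 < 1e-10) return(0)          # disconnected
  l2 / lmax
}

#' @rdname graph_metrics
#' @param modules integer/character vector assigning every node to a module.
#' @return `participation_coefficient`: per-node
#'   `1 - sum_m (k_im / k_i)^2` (0 for isolated nodes).
#' @export
participation_coefficient <- function(A, modules) {
  A <- check_adjacency(A)
  n <- nrow(A)
  if (length(modules) != n || anyNA(modules))
    stop("modules must assign every node to a module")
  modules <- as.integer(factor(modules))
  k <- rowSums(A)
  vapply(seq_len(n), function(i) {
    if (k[i] == 0) return(0)
    kim <- tapply(A[i, ], modules, sum)
    1 - sum((kim / k[i])^2)
  }, numeric(1))
}

#' @rdname graph_metrics
#' @param values metric values aligned with `densities`.
#' @param densities the density grid.
#' @return `metric_auc`: trapezoidal integral of `values` over the density
#'   grid, normalized by the grid span (so a constant integrates to
#'   itself).
#' @export
metric_auc <- function(values, densities) {
  if (length(values) != length(densities)) stop("values/densities misaligned")
  if (length(densities) < 2) stop("need at least 2 densities")
  o <- order(densities)
  d <- densities[o]
  v <- values[o]
  sum(diff(d) * (head(v, -1) + v[-1]) / 2) / (max(d) - min(d))
}

#' @rdname graph_metrics
#' @param seed integer seed (module detection is deterministic given the
#'   graph and seed).
#' @return `detect_modules`: integer module membership by greedy modularity
#'   (Louvain) on each connected component.
#' @export
detect_modules <- function(A, seed = 1L) {
  A <- check_adjacency(A)
  .seed_guard(seed)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  as.integer(igraph::membership(igraph::cluster_louvain(g)))
}

#' All global measures of one network
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @return Named list: `assortativity`, `hierarchy`, `clustering_coefficient`,
#'   `global_efficiency`, `local_efficiency`, `synchronization`,
#'   `characteristic_path_length`, `n_unreachable_pairs`.
#' @export
global_metrics <- function(A) {
  A <- check_adjacency(A)
  cpl <- characteristic_path_length(A)
  list(
    assortativity = if (sum(A) > 0) assortativity_coefficient(A) else NA_real_,
    hierarchy = hierarchy_coefficient(A),
    clustering_coefficient = clustering_coefficient(A)$mean,
    global_efficiency = global_efficiency(A),
    local_efficiency = local_efficiency(A)$mean,
    synchronization = synchronizability(A),
    characteristic_path_length = cpl$L,
    n_unreachable_pairs = cpl$n_unreachable_pairs
  )
}

#' All nodal measures of one network
#'
#' @param A binary symmetric adjacency matrix, zero diagonal.
#' @param modules optional module assignment for the participation
#'   coefficient; detected by [detect_modules()] when absent.
#' @param seed seed for module detection.
#' @return data.frame with one row per node: `degree`, `clustering`,
#'   `shortest_path_length` (mean distance to reachable nodes),
#'   `nodal_efficiency`, `local_efficiency`, `participation`.
#' @export
nodal_metrics <- function(A, modules = NULL, seed = 1L) {
  A <- check_adjacency(A)
  if (is.null(modules)) modules <- detect_modules(A, seed)
  D <- cpp_shortest_paths(A)
  li <- apply(D, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    if (length(d)) mean(d) else NA_real_
  })
  data.frame(
    node = if (!is.null(rownames(A))) rownames(A) else seq_len(nrow(A)),
    degree = degree_centrality(A),
    clustering = clustering_coefficient(A)$nodal,
    shortest_path_length = as.numeric(li),
    nodal_efficiency = nodal_efficiency(A),
    local_efficiency = local_efficiency(A)$nodal,
    participation = participation_coefficient(A, modules),
    stringsAsFactors = FALSE
  )
}

#' Metrics across a density sweep with AUC integration
#'
#' Computes [global_metrics()] and nodal degree for every density of an
#' [build_adjacency_series()] and integrates each over the sweep with
#' [metric_auc()].
#'
#' @param series an `adjacency_series`.
#' @return List with `global` (data.frame: density x metric), `global_auc`
#'   (named vector), `degree` (matrix: density x node) and `degree_auc`
#'   (vector, the AUC-integrated degree centrality used for hub decisions).
#' @export
metrics_over_series <- function(series) {
  stopifnot(inherits(series, "adjacency_series"))
  gm <- lapply(series$adjacency, global_metrics)
  global <- do.call(rbind, lapply(seq_along(gm), function(i)
    data.frame(density = series$densities[i],
               as.data.frame(gm[[i]], stringsAsFactors = FALSE))))
  deg <- do.call(rbind, lapply(series$adjacency, function(A)
    as.numeric(degree_centrality(A))))
  colnames(deg) <- series$roi_labels
  num_cols <- setdiff(names(global), c("density", "n_unreachable_pairs"))
  auc <- vapply(num_cols, function(m) {
    v <- global[[m]]
    ok <- is.finite(v)
    if (sum(ok) < 2) return(NA_real_)
    metric_auc(v[ok], global$density[ok])
  }, numeric(1))
  list(global = global, global_auc = auc, degree = deg,
       degree_auc = apply(deg, 2, metric_auc, densities = series$densities))
}
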