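#' Empirical covariance of an SUVR matrix
#'
#' With `standardize = TRUE` (the default) ROIs are scaled to unit variance,
#' i.e. the empirical correlation matrix is returned, so the graphical lasso
#' penalty acts on a common scale across regions.
#'
#' @param x a [suvr_matrix()] or a plain numeric matrix (subjects x ROIs).
#' @param standardize logical; return the correlation matrix (default) or
#'   the raw covariance.
#' @return A p x p symmetric matrix with ROI dimnames.
#' @export
sample_covariance <- function(x, standardize = TRUE) {
  X <- if (inherits(x, "suvr_matrix")) x$values else as.matrix(x)
  if (nrow(X) < 2) stop("need at least 2 subjects")
  v <- apply(X, 2, var)
  if (standardize && any(v <= 0))
    stop("zero-variance ROI column(s): ",
         paste(colnames(X)[v <= 0], collapse = ", "))
  S <- if (standardize) {
    C <- cor(X)
    diag(C) <- 1
    C
  } else cov(X)
  S
}

#' Sparse inverse covariance estimation (graphical lasso)
#'
#' Maximizes the L1-penalized Gaussian log-likelihood
#' \deqn{\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\ne j}|\Theta_{ij}|}
#' by block coordinate descent (one lasso regression per column of the
#' working covariance). Off-diagonal zeros of the estimated precision
#' \eqn{\Theta} encode conditional independence, i.e. absent edges of the
#' metabolic network.
#'
#' @param S symmetric covariance/correlation matrix with positive diagonal.
#' @param lambda penalty \eqn{\ge 0}. At `lambda = 0` and invertible `S`
#'   the unpenalized MLE `solve(S)` is returned.
#' @param tol relative convergence tolerance on the working covariance.
#' @param max_iter maximum outer sweeps.
#' @return An object of class `precision_matrix`: list with `theta`,
#'   `lambda`, `converged`, `n_iter`, `objective`, `kkt` (max KKT residual),
#'   `density` (realized off-diagonal edge density).
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-4, max_iter = 200) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("S must be a symmetric matrix")
  if (any(diag(S) <= 0)) stop("S must have a positive diagonal")
  if (lambda < 0) stop("lambda must be >= 0")
  S <- (S + t(S)) / 2
  fit <- cpp_glasso(S, lambda, tol, max_iter)
  if (!fit$converged)
    warning("graphical lasso did not converge in ", max_iter, " sweeps")
  theta <- fit$theta
  dimnames(theta) <- dimnames(S)
  structure(list(theta = theta, lambda = lambda, converged = fit$converged,
                 n_iter = fit$n_iter, objective = fit$objective,
                 kkt = fit$kkt, density = fit$density),
            class = "precision_matrix")
}

#' @export
print.precision_matrix <- function(x, ...) {
  cat(sprintf(
    "<precision_matrix> p=%d lambda=%.4g density=%.3f converged=%s (%d sweeps)\n",
    nrow(x$theta), x$lambda, x$density, x$converged, x$n_iter))
  invisible(x)
}

#' Penalty achieving a target network density
#'
#' Edge count is non-increasing in `lambda`, so the penalty matching a
#' target off-diagonal density is found by bisection (warm-started solves).
#' If the target is unreachable (density plateaus above it even at the
#' smallest admissible penalty), the closest achievable fit is returned
#' with a warning.
#'
#' @inheritParams graphical_lasso
#' @param target_density requested fraction of present edges, in (0, 1);
#'   0 is allowed and returns an empty graph.
#' @param tol_density acceptable |realized - target| density gap.
#' @param lambda_min_frac lower end of the bisection bracket as a fraction
#'   of `max|S_ij|`.
#' @param max_bisect maximum bisection steps.
#' @return List with `lambda`, `fit` (a `precision_matrix`), `density`.
#' @export
lambda_for_density <- function(S, target_density, tol_density = 0.01,
                               tol = 1e-4, max_iter = 200,
                               lambda_min_frac = 1e-3, max_bisect = 30) {
  S <- as.matrix(S)
  if (target_density < 0 || target_density >= 1)
    stop("target_density must be in [0, 1)")
  S <- (S + t(S)) / 2
  res <- cpp_lambda_for_density(S, target_density, tol_density, tol,
                                max_iter, lambda_min_frac, max_bisect)
  if (isTRUE(res$plateau))
    warning(sprintf(
      "target density %.3f unreachable; closest achieved %.3f at lambda %.4g",
      target_density, res$density, res$lambda))
  theta <- res$theta
  dimnames(theta) <- dimnames(S)
  fit <- structure(list(theta = theta, lambda = res$lambda,
                        converged = res$converged, n_iter = NA_integer_,
                        objective = NA_real_, kkt = NA_real_,
                        density = res$density),
                   class = "precision_matrix")
  list(lambda = res$lambda, fit = fit, density = res$density)
}

#' Partial correlations implied by a precision matrix
#'
#' \eqn{r_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}}.
#'
#' @param theta symmetric precision matrix.
#' @return Matrix of partial correlations with unit diagonal.
#' @export
partial_correlation <- function(theta) {
  d <- sqrt(diag(theta))
  r <- -theta / outer(d, d)
  diag(r) <- 1
  r
}

#' Binary adjacency from a precision matrix
#'
#' @param theta precision matrix.
#' @param zero_tol entries with |value| below this are treated as absent.
#' @return 0/1 symmetric matrix with zero diagonal.
#' @export
adjacency_from_precision <- function(theta, zero_tol = 1e-8) {
  A <- (abs(theta) > zero_tol) * 1
  diag(A) <- 0
  A
}

#' Group network estimates across a density sweep
#'
#' For each target density: find the matching penalty, fit the graphical
#' lasso, binarize the precision support, and derive the partial-correlation
#' edge weights. Groups are compared at matched densities (not matched
#' penalties), the standard practice for SICE-based PET connectomes.
#'
#' @param x a [suvr_matrix()] (all its subjects form one group) or numeric
#'   matrix.
#' @param densities increasing vector of target densities in (0, 1);
#'   default sweep 0.10 to 0.40 in steps of 0.02.
#' @inheritParams lambda_for_density
#' @return An object of class `adjacency_series`: list with `densities`,
#'   `adjacency` (list of 0/1 matrices), `weights` (list of
#'   partial-correlation matrices masked to retained edges), `lambdas`,
#'   `realized_densities`, `roi_labels`.
#' @export
build_adjacency_series <- function(x, densities = seq(0.10, 0.40, by = 0.02),
                                   tol_density = 0.01, tol = 1e-4,
                                   max_iter = 200) {
  if (is.unsorted(densities, strictly = TRUE) ||
      any(densities <= 0 | densities >= 1))
    stop("densities must be strictly increasing and inside (0, 1)")
  S <- sample_covariance(x)
  adjacency <- weights <- vector("list", length(densities))
  lambdas <- realized <- numeric(length(densities))
  for (i in seq_along(densities)) {
    res <- lambda_for_density(S, densities[i], tol_density = tol_density,
                              tol = tol, max_iter = max_iter)
    A <- adjacency_from_precision(res$fit$theta)
    W <- partial_correlation(res$fit$theta) * A
    adjacency[[i]] <- A
    weights[[i]] <- W
    lambdas[i] <- res$lambda
    realized[i] <- res$density
  }
  structure(list(densities = densities, adjacency = adjacency,
                 weights = weights, lambdas = lambdas,
                 realized_densities = realized,
                 roi_labels = colnames(S)),
            class = "adjacency_series")
}

#' @export
print.adjacency_series <- function(x, ...) {
  cat(sprintf("<adjacency_series> p=%d, %d densities [%.2f..%.2f]\n",
              length(x$roi_labels), length(x$densities),
              min(x$densities), max(x$densities)))
  invisible(x)
}

#' Bootstrap test of edge-weight differences between two groups
#'
#' Subjects are resampled with replacement within each group `B` times; at
#' each resample both group networks are re-estimated at the matched target
#' density and the per-edge difference of partial-correlation weights
#' (group A minus group B) is recorded. Edges whose percentile confidence
#' interval excludes zero are labeled `enhanced` (A > B) or `weakened`
#' (uncorrected; apply [fdr_bh()] to `p_boot` downstream).
#'
#' @param xa,xb [suvr_matrix()] objects (or matrices) for the two groups,
#'   same ROIs.
#' @param density target network density for both groups.
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level of the percentile interval.
#' @param seed integer seed.
#' @return data.frame with one row per edge: `roi_i`, `roi_j`, `observed`
#'   weight difference, bootstrap `mean`, `lo`, `hi`, two-sided `p_boot`,
#'   and `label`.
#' @export
bootstrap_edges <- function(xa, xb, density = 0.15, B = 1000, level = 0.95,
                            seed = NULL) {
  Xa <- if (inherits(xa, "suvr_matrix")) xa$values else as.matrix(xa)
  Xb <- if (inherits(xb, "suvr_matrix")) xb$values else as.matrix(xb)
  if (ncol(Xa) != ncol(Xb)) stop("groups must share the ROI set")
  if (nrow(Xa) < 3 || nrow(Xb) < 3)
    stop("each group needs at least 3 subjects to resample")
  if (B < 100) stop("B must be >= 100")
  .seed_guard(seed)
  p <- ncol(Xa)
  weight_of <- function(X) {
    res <- lambda_for_density(suppressWarnings(sample_covariance(X)), density)
    partial_correlation(res$fit$theta) * adjacency_from_precision(res$fit$theta)
  }
  ut <- upper.tri(matrix(0, p, p))
  obs <- (weight_of(Xa) - weight_of(Xb))[ut]
  diffs <- matrix(0, B, sum(ut))
  for (b in seq_len(B)) {
    ra <- Xa[sample.int(nrow(Xa), replace = TRUE), , drop = FALSE]
    rb <- Xb[sample.int(nrow(Xb), replace = TRUE), , drop = FALSE]
    diffs[b, ] <- suppressWarnings((weight_of(ra) - weight_of(rb))[ut])
  }
  alpha <- (1 - level) / 2
  lo <- apply(diffs, 2, quantile, probs = alpha)
  hi <- apply(diffs, 2, quantile, probs = 1 - alpha)
  p_boot <- apply(diffs, 2, function(d) {
    f <- mean(d > 0)
    2 * min(f, 1 - f)
  })
  labs <- if (!is.null(colnames(Xa))) colnames(Xa) else sprintf("roi%03d", 1:p)
  idx <- which(ut, arr.ind = TRUE)
  label <- rep("ns", length(obs))
  label[lo > 0] <- "enhanced"
  label[hi < 0] <- "weakened"
  data.frame(roi_i = labs[idx[, 1]], roi_j = labs[idx[, 2]],
             observed = obs, mean = colMeans(diffs), lo = lo, hi = hi,
             p_boot = p_boot, label = label, stringsAsFactors = FALSE)
}

#' Write an adjacency series as CSV matrices and an edge-list TSV
#'
#' @param series an [build_adjacency_series()] result.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix, e.g. the group label.
#' @return Invisibly, the paths written.
#' @export
write_adjacency_series <- function(series, dir, prefix = "group") {
  stopifnot(inherits(series, "adjacency_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  edges <- NULL
  for (i in seq_along(series$densities)) {
    d <- series$densities[i]
    fa <- file.path(dir, sprintf("%s_adjacency_d%.2f.csv", prefix, d))
    fw <- file.path(dir, sprintf("%s_weights_d%.2f.csv", prefix, d))
    write.csv(series$adjacency[[i]], fa)
    write.csv(series$weights[[i]], fw)
    paths <- c(paths, fa, fw)
    W <- series$weights[[i]]
    ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    if (nrow(ut))
      edges <- rbind(edges, data.frame(
        roi_i = series$roi_labels[ut[, 1]], roi_j = series$roi_labels[ut[, 2]],
        density = d, weight = W[ut], stringsAsFactors = FALSE))
  }
  fe <- file.path(dir, paste0(prefix, "_edges.tsv"))
  write.table(edges, fe, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(paths, fe))
}
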