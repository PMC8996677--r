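#' Density-matched network statistic for permutation testing
#'
#' Describes a group-level network statistic of the SICE chain: empirical
#' correlation, graphical lasso at the penalty matching `density`, binary
#' support, then a global graph measure. Used as the `statistic` argument
#' of [permutation_test()], where it dispatches to a compiled loop that
#' re-estimates the full chain inside every permutation.
#'
#' @param metric one of `"global_efficiency"`, `"clustering_coefficient"`,
#'   `"characteristic_path_length"`.
#' @param density target network density.
#' @param tol_density density matching tolerance.
#' @return An object of class `network_statistic`.
#' @export
network_statistic <- function(metric = c("global_efficiency",
                                         "clustering_coefficient",
                                         "characteristic_path_length"),
                              density = 0.15, tol_density = 0.01) {
  metric <- match.arg(metric)
  structure(list(metric = metric,
                 metric_id = match(metric, c("global_efficiency",
                                             "clustering_coefficient",
                                             "characteristic_path_length")),
                 density = density, tol_density = tol_density,
                 tol = 1e-4, max_iter = 200, lambda_min_frac = 1e-3,
                 max_bisect = 12),
            class = "network_statistic")
}

eval_network_statistic <- function(stat, X) {
  res <- suppressWarnings(lambda_for_density(
    sample_covariance(X), stat$density, tol_density = stat$tol_density,
    tol = stat$tol, max_iter = stat$max_iter,
    lambda_min_frac = stat$lambda_min_frac, max_bisect = stat$max_bisect))
  cpp_bin_metric(adjacency_from_precision(res$fit$theta), stat$metric_id)
}

as_stat_fun <- function(statistic) {
  if (inherits(statistic, "network_statistic"))
    return(function(Xa, Xb)
      eval_network_statistic(statistic, Xa) - eval_network_statistic(statistic, Xb))
  if (is.function(statistic)) return(statistic)
  stop("statistic must be a function(Xa, Xb) or a network_statistic()")
}

perm_result <- function(observed, perms, n_perm, seed, two_sided, correction) {
  exceed <- if (two_sided) sum(abs(perms) >= abs(observed))
            else sum(perms >= observed)
  p <- if (correction) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  structure(list(observed = observed, perm_mean = mean(perms),
                 perm_sd = sd(perms), p_value = p, n_perm = n_perm,
                 seed = seed, two_sided = two_sided,
                 perms = perms),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed diff = %.4g, p = %.4g (%d permutations, %s)\n",
    x$observed, x$p_value, x$n_perm,
    if (x$two_sided) "two-sided" else "one-sided"))
  invisible(x)
}

#' Nonparametric permutation test of a group difference
#'
#' Subject labels are randomly re-assigned between the two groups
#' (preserving the group sizes) `n_perm` times; the statistic — by default
#' a full re-estimation of the network chain — is recomputed on every
#' relabeling. The p-value is the fraction of permuted differences whose
#' magnitude reaches the observed one (two-sided default; the plain
#' fraction can be 0 — set `correction = TRUE` for the (b+1)/(B+1) form).
#'
#' @param xa,xb [suvr_matrix()] objects or numeric matrices (subjects x
#'   ROIs) for the two groups.
#' @param statistic a [network_statistic()] (fast compiled path) or a
#'   function `f(Xa, Xb)` returning a scalar difference.
#' @param n_perm number of permutations (default 5000, >= 100).
#' @param seed integer seed.
#' @param two_sided compare absolute differences (default) or the signed
#'   difference.
#' @param correction use the (b+1)/(B+1) p-value instead of the plain
#'   fraction.
#' @return A `permutation_result`: `observed`, `perm_mean`, `perm_sd`,
#'   `p_value`, `n_perm`, `seed`, `two_sided`, and the permutation
#'   distribution `perms`.
#' @export
permutation_test <- function(xa, xb,
                             statistic = network_statistic(),
                             n_perm = 5000, seed = NULL, two_sided = TRUE,
                             correction = FALSE) {
  Xa <- if (inherits(xa, "suvr_matrix")) xa$values else as.matrix(xa)
  Xb <- if (inherits(xb, "suvr_matrix")) xb$values else as.matrix(xb)
  if (ncol(Xa) != ncol(Xb)) stop("groups must share the ROI set")
  if (n_perm < 100) stop("n_perm must be >= 100")
  .seed_guard(seed)
  na <- nrow(Xa)
  nb <- nrow(Xb)
  if (inherits(statistic, "network_statistic")) {
    res <- cpp_perm_netstat(Xa, Xb, statistic$density, statistic$metric_id,
                            as.integer(n_perm), statistic$tol_density,
                            statistic$tol, statistic$max_iter,
                            statistic$lambda_min_frac, statistic$max_bisect)
    return(perm_result(res$observed, res$perms, n_perm, seed, two_sided,
                       correction))
  }
  f <- as_stat_fun(statistic)
  observed <- f(Xa, Xb)
  X <- rbind(Xa, Xb)
  perms <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(na + nb)
    ia <- idx[seq_len(na)]
    stopifnot(length(ia) == na)  # group sizes preserved by construction
    f(X[ia, , drop = FALSE], X[idx[(na + 1):(na + nb)], , drop = FALSE])
  }, numeric(1))
  perm_result(observed, perms, n_perm, seed, two_sided, correction)
}

#' Exact (exhaustive) permutation test
#'
#' Enumerates every assignment of the pooled subjects into groups of the
#' original sizes; feasible when `choose(na + nb, na) <= 200000`. Serves
#' as the exact reference for the Monte-Carlo [permutation_test()].
#'
#' @inheritParams permutation_test
#' @return A `permutation_result` with `n_perm = choose(na + nb, na)`.
#' @export
exact_permutation_test <- function(xa, xb, statistic = network_statistic(),
                                   two_sided = TRUE) {
  Xa <- if (inherits(xa, "suvr_matrix")) xa$values else as.matrix(xa)
  Xb <- if (inherits(xb, "suvr_matrix")) xb$values else as.matrix(xb)
  na <- nrow(Xa)
  nb <- nrow(Xb)
  n_assign <- choose(na + nb, na)
  if (n_assign > 200000)
    stop("too many assignments to enumerate (", n_assign, " > 200000)")
  f <- as_stat_fun(statistic)
  observed <- f(Xa, Xb)
  X <- rbind(Xa, Xb)
  sets <- combn(na + nb, na)
  perms <- apply(sets, 2, function(ia)
    f(X[ia, , drop = FALSE], X[-ia, , drop = FALSE]))
  perm_result(observed, perms, as.integer(n_assign), NULL, two_sided,
              correction = FALSE)
}

#' GLM contrast of a per-subject measure between groups
#'
#' Ordinary least squares of the standardized response on an intercept, a
#' group indicator and optional nuisance covariates (age, sex); reports
#' the standardized group coefficient (an effect size in SD units of the
#' response), its t statistic and two-sided p-value. With no covariates the
#' t equals the classical pooled-variance two-sample t.
#'
#' @param y numeric per-subject values.
#' @param group two-level factor (first level is the reference).
#' @param covariates optional data.frame of numeric covariates.
#' @return List: `beta` (standardized group effect), `t`, `p`, `df`.
#' @export
glm_contrast <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (sd(y) == 0) return(list(beta = 0, t = 0, p = 1,
                              df = length(y) - 2 -
                                if (is.null(covariates)) 0 else ncol(covariates)))
  ys <- (y - mean(y)) / sd(y)
  df_design <- data.frame(g = as.numeric(group) - 1)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(col)
      if (is.numeric(col)) col else as.numeric(factor(col)))
    df_design <- cbind(df_design, covariates)
  }
  X <- cbind(1, as.matrix(df_design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-(qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- lm(ys ~ ., data = df_design)
  sm <- summary(fit)$coefficients
  list(beta = unname(sm["g", "Estimate"]), t = unname(sm["g", "t value"]),
       p = unname(sm["g", "Pr(>|t|)"]), df = fit$df.residual)
}

#' Effect-size filter on standardized betas
#'
#' Flags effects with `|beta| > threshold` (strict). The magnitude is used
#' so that both decreases and increases pass the filter.
#'
#' @param betas numeric standardized effect sizes.
#' @param threshold effect-size cutoff (default 0.8).
#' @return Logical flags.
#' @export
effect_size_filter <- function(betas, threshold = 0.8) {
  if (any(!is.finite(betas))) stop("betas must be finite")
  abs(betas) > threshold
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure: adjusted p-values by the monotone
#' cumulative-minimum construction; rejection when adjusted p <= q.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical) and `p_adjusted`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj)
}
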