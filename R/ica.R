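#' Estimate the number of ICA components by MDL order selection
#'
#' Information-theoretic order selection on the PCA eigenvalue spectrum of
#' the subjects x voxels data (the Wax-Kailath minimum description length
#' criterion for the number of signals in iid Gaussian noise). Voxels are
#' the samples, subjects the observed dimensions. If the spectrum is
#' exactly rank deficient the numeric rank is returned directly.
#'
#' @param X subjects x voxels matrix (>= 3 subjects).
#' @return Estimated component count in `[1, subjects - 1]`.
#' @export
estimate_n_components <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects")
  Xc <- X - rowMeans(X)
  V <- ncol(X)
  ev <- eigen(tcrossprod(Xc) / V, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (max(ev) <= 0) stop("data have zero variance")
  pos <- ev > 1e-10 * max(ev)
  r <- sum(pos)
  if (r < n) return(max(1L, min(r, n - 1L)))  # exactly low-rank data
  mdl <- vapply(0:(n - 2), function(k) {
    tail_ev <- ev[(k + 1):n]
    g <- exp(mean(log(tail_ev)))
    a <- mean(tail_ev)
    -V * (n - k) * log(g / a) + 0.5 * k * (2 * n - k + 1) * log(V)
  }, numeric(1))
  max(1L, as.integer(which.min(mdl) - 1L))
}

#' PCA whitening of subjects-by-voxels data
#'
#' Row-centers the data (per-subject mean over voxels), then projects onto
#' the top `k` principal components and rescales them to identity
#' covariance across voxels. The returned transforms round-trip to the
#' rank-k PCA reconstruction of the centered data.
#'
#' @param X subjects x voxels matrix.
#' @param k number of retained components (`<= min(dim(X))`).
#' @return List: `y` (k x voxels whitened matrix with `y %*% t(y) / V = I`),
#'   `whitening` (k x subjects), `dewhitening` (subjects x k),
#'   `row_means`, `k`.
#' @export
pca_whiten <- function(X, k) {
  X <- as.matrix(X)
  if (k > min(dim(X))) stop("k exceeds the rank bound min(subjects, voxels)")
  rm_ <- rowMeans(X)
  Xc <- X - rm_
  V <- ncol(X)
  sv <- svd(Xc, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  if (any(d <= 1e-12 * sv$d[1]))
    stop("requested k exceeds the numerical rank of the data")
  whitening <- sqrt(V) * diag(1 / d, k) %*% t(sv$u)
  dewhitening <- sv$u %*% diag(d, k) / sqrt(V)
  y <- whitening %*% Xc
  list(y = y, whitening = whitening, dewhitening = dewhitening,
       row_means = rm_, k = k)
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with the logistic nonlinearity (entropy
#' maximization / mutual information minimization), applied to PCA-whitened
#' data in the spatial orientation: subjects are mixtures, voxels are
#' samples, components are independent spatial maps. The learning rate is
#' annealed; a diverging step is rolled back with a halved rate.
#' Components are ordered by explained variance and signs are fixed so the
#' maximum-magnitude voxel of each map is positive, making the result
#' deterministic under a fixed seed.
#'
#' @param white a [pca_whiten()] result (or a k x voxels whitened matrix).
#' @param seed integer seed for the unmixing initialisation.
#' @param lr initial learning rate.
#' @param max_iter maximum iterations (default 512).
#' @param tol convergence threshold on the relative weight update norm.
#' @return An object of class `ica_result`: `n_components`, `mixing`
#'   (subjects x components, `NULL` when raw whitened input was given),
#'   `maps` (components x voxels), `z_maps` (per-component z-scored maps),
#'   `unmixing`, `converged`, `n_iter`, `final_update`, `seed`.
#' @export
infomax_ica <- function(white, seed = 1L, lr = 0.01, max_iter = 512,
                        tol = 1e-7) {
  if (is.matrix(white)) white <- list(y = white, dewhitening = NULL,
                                      k = nrow(white))
  Y <- white$y
  k <- nrow(Y)
  V <- ncol(Y)
  .seed_guard(seed)
  W <- qr.Q(qr(matrix(rnorm(k * k), k)))
  lr0 <- lr
  I_k <- diag(k)
  converged <- FALSE
  upd <- NA_real_
  it <- 0
  dW_prev <- NULL
  while (it < max_iter) {
    it <- it + 1
    U <- W %*% Y
    G <- 1 / (1 + exp(-U))
    dW <- lr * (I_k + ((1 - 2 * G) %*% t(U)) / V) %*% W
    if (any(!is.finite(dW)) || max(abs(dW)) > 1e3) {
      lr <- lr / 2  # step diverged: retry smaller
      next
    }
    # adapt the step size: grow it while successive updates agree, shrink
    # it when they oppose (overshoot around the fixed point)
    if (!is.null(dW_prev)) {
      if (sum(dW * dW_prev) < 0) lr <- lr * 0.7
      else lr <- min(lr * 1.05, lr0 * 20)
    }
    dW_prev <- dW
    W <- W + dW
    upd <- sqrt(sum(dW^2)) / sqrt(sum(W^2))
    if (upd < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Infomax did not reach tol ", tol, " in ", max_iter,
            " iterations (final relative update ", signif(upd, 3), ")")
  maps <- W %*% Y
  mixing <- if (!is.null(white$dewhitening)) white$dewhitening %*% solve(W)
            else NULL
  # order by explained variance of each component's contribution
  map_ss <- rowSums(maps^2) / V
  mix_ss <- if (!is.null(mixing)) colSums(mixing^2) else rep(1, k)
  ord <- order(map_ss * mix_ss, decreasing = TRUE)
  maps <- maps[ord, , drop = FALSE]
  W <- W[ord, , drop = FALSE]
  if (!is.null(mixing)) mixing <- mixing[, ord, drop = FALSE]
  sgn <- vapply(seq_len(k), function(c_i)
    sign(maps[c_i, which.max(abs(maps[c_i, ]))]), numeric(1))
  sgn[sgn == 0] <- 1
  maps <- maps * sgn
  W <- W * sgn
  if (!is.null(mixing)) mixing <- sweep(mixing, 2, sgn, `*`)
  z_maps <- (maps - rowMeans(maps)) / apply(maps, 1, sd)
  structure(list(n_components = k, mixing = mixing, maps = maps,
                 z_maps = z_maps, unmixing = W, converged = converged,
                 n_iter = it, final_update = upd, seed = seed),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %d components, %s after %d iterations\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Threshold a z-scored map
#'
#' Positive-tail threshold `z > z_cut` (strict) by default; `two_tailed`
#' thresholds `|z| > z_cut`.
#'
#' @param z_map numeric vector/array of z-scores.
#' @param z_cut threshold (default 1.96).
#' @param two_tailed use `|z|`.
#' @return Logical mask with the shape of `z_map`.
#' @export
threshold_z <- function(z_map, z_cut = 1.96, two_tailed = FALSE) {
  if (two_tailed) abs(z_map) > z_cut else z_map > z_cut
}

#' Match ICA components to subnetwork templates
#'
#' Greedy one-to-one assignment: repeatedly pick the (template, component)
#' pair with the highest spatial correlation between the template mask
#' (0/1) and the component's |z| map, without replacement. Ties break to
#' the lowest component index.
#'
#' @param z_maps components x voxels matrix of z-scores (or an
#'   `ica_result`).
#' @param templates named list of logical masks (arrays or vectors) on the
#'   same grid.
#' @return data.frame: `template`, `component`, `correlation`.
#' @export
match_templates <- function(z_maps, templates) {
  if (inherits(z_maps, "ica_result")) z_maps <- z_maps$z_maps
  if (length(templates) > nrow(z_maps))
    stop("more templates than components")
  if (is.null(names(templates)))
    names(templates) <- sprintf("template%d", seq_along(templates))
  tmpl <- vapply(templates, function(m) {
    v <- as.numeric(m)
    if (length(v) != ncol(z_maps)) stop("template grid mismatch")
    if (!any(v > 0)) stop("empty template mask")
    v
  }, numeric(ncol(z_maps)))
  cors <- matrix(NA_real_, length(templates), nrow(z_maps))
  for (t_i in seq_along(templates))
    for (c_i in seq_len(nrow(z_maps)))
      cors[t_i, c_i] <- cor(tmpl[, t_i], abs(z_maps[c_i, ]))
  out <- data.frame(template = character(0), component = integer(0),
                    correlation = numeric(0), stringsAsFactors = FALSE)
  avail_t <- seq_along(templates)
  avail_c <- seq_len(nrow(z_maps))
  while (length(avail_t)) {
    sub <- cors[avail_t, avail_c, drop = FALSE]
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    # tie-break: lowest component index, then lowest template index
    hit <- hit[order(avail_c[hit[, 2]], avail_t[hit[, 1]]), , drop = FALSE]
    t_i <- avail_t[hit[1, 1]]
    c_i <- avail_c[hit[1, 2]]
    out <- rbind(out, data.frame(template = names(templates)[t_i],
                                 component = c_i, correlation = best,
                                 stringsAsFactors = FALSE))
    avail_t <- setdiff(avail_t, t_i)
    avail_c <- setdiff(avail_c, c_i)
  }
  out[order(match(out$template, names(templates))), , drop = FALSE]
}

#' Group comparison of connectivity within a subnetwork
#'
#' Restricted to a subnetwork's ROIs (e.g., the DMN or SN node set derived
#' from template-matched ICA components), compares the two groups':
#' per-edge partial-correlation weights by permutation (increased /
#' decreased at `alpha_edge`, uncorrected) and per-node SUVR levels by GLM
#' contrast with available covariates at the stricter `alpha_node`.
#'
#' @param xa,xb [suvr_matrix()] objects restricted to the network's ROIs
#'   (>= 3 ROIs), control-like group first.
#' @param density matched network density for the edge weights.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param alpha_edge edge-level significance threshold (default 0.05).
#' @param alpha_node node-level threshold (default 0.005, uncorrected).
#' @return List of data.frames `edges` (`roi_i`, `roi_j`, `observed`,
#'   `p_perm`, `label`) and `nodes` (`roi`, `beta`, `t`, `p`, `flag`).
#' @export
compare_network <- function(xa, xb, density = 0.15, n_perm = 5000,
                            seed = NULL, alpha_edge = 0.05,
                            alpha_node = 0.005) {
  stopifnot(inherits(xa, "suvr_matrix"), inherits(xb, "suvr_matrix"))
  if (!identical(xa$roi_labels, xb$roi_labels))
    stop("groups must share the network ROI set")
  p <- ncol(xa$values)
  if (p < 3) stop("network needs at least 3 ROIs")
  .seed_guard(seed)
  weight_of <- function(X) {
    res <- suppressWarnings(lambda_for_density(sample_covariance(X), density,
                                               max_bisect = 12))
    partial_correlation(res$fit$theta) * adjacency_from_precision(res$fit$theta)
  }
  ut <- upper.tri(matrix(0, p, p))
  Xa <- xa$values
  Xb <- xb$values
  obs <- (weight_of(Xa) - weight_of(Xb))[ut]
  X <- rbind(Xa, Xb)
  na <- nrow(Xa)
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(nrow(X))
    d <- (weight_of(X[idx[seq_len(na)], , drop = FALSE]) -
            weight_of(X[idx[-seq_len(na)], , drop = FALSE]))[ut]
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p_perm <- exceed / n_perm
  idx_ut <- which(ut, arr.ind = TRUE)
  label <- rep("ns", length(obs))
  sig <- p_perm < alpha_edge
  label[sig & obs > 0] <- "increased"
  label[sig & obs < 0] <- "decreased"
  edges <- data.frame(roi_i = xa$roi_labels[idx_ut[, 1]],
                      roi_j = xa$roi_labels[idx_ut[, 2]],
                      observed = obs, p_perm = p_perm, label = label,
                      stringsAsFactors = FALSE)
  covs <- if (!is.null(xa$covariates) && !is.null(xb$covariates))
    rbind(xa$covariates, xb$covariates) else NULL
  grp <- factor(rep(c("a", "b"), c(nrow(Xa), nrow(Xb))), levels = c("b", "a"))
  nodes <- do.call(rbind, lapply(seq_len(p), function(j) {
    g <- glm_contrast(X[, j], grp, covs)
    data.frame(roi = xa$roi_labels[j], beta = g$beta, t = g$t, p = g$p,
               flag = g$p < alpha_node, stringsAsFactors = FALSE)
  }))
  list(edges = edges, nodes = nodes)
}
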