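#' Synthetic volume dataset with planted spatial sources
#'
#' Emulates the input of the spatial ICA stage: each subject's volume is a
#' linear mixture of a few compact spatial source maps (Gaussian blobs,
#' truncated to a compact support, hence spatially super-Gaussian) plus
#' iid Gaussian noise. A toy label atlas covering the blobs (plus a corner
#' reference region for SUVR normalization) and the full ground truth
#' (mixing matrix, source maps, binary templates) are returned so that
#' component recovery and template matching can be scored exactly.
#'
#' @param dims 3D grid dimensions (each >= 10).
#' @param n_subjects number of subjects (> `n_sources`).
#' @param n_sources number of planted sources (>= 2).
#' @param noise_sd iid voxel noise standard deviation.
#' @param seed integer seed.
#' @param spacing voxel spacing in mm.
#' @param mixing_mean,mixing_sd distribution of the subject loadings.
#' @return List: `volumes` (list of [volume()]), `mixing`
#'   (subjects x sources), `maps` (sources x voxels matrix, grid dims in
#'   attribute `dims`), `templates` (named list of logical arrays),
#'   `atlas` (an [roi_atlas()] whose labels 1..k cover the blob cores and
#'   whose reference region sits in a blob-free corner), `seed`.
#' @export
make_volume_dataset <- function(dims = c(24, 24, 16), n_subjects = 30,
                                n_sources = 3, noise_sd = 0.1, seed = 1L,
                                spacing = c(2, 2, 2), mixing_mean = 1,
                                mixing_sd = 1) {
  if (n_sources < 2) stop("need at least 2 sources")
  if (n_subjects <= n_sources) stop("n_subjects must exceed n_sources")
  if (any(dims < 10)) stop("grid dims too small for compact sources")
  .seed_guard(seed)
  n_vox <- prod(dims)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  margin <- 4
  min_sep <- 0.45 * min(dims)
  centers <- matrix(NA_real_, n_sources, 3)
  for (c_i in seq_len(n_sources)) {
    placed <- FALSE
    for (try_i in 1:200) {
      cand <- vapply(1:3, function(a) runif(1, margin + 1, dims[a] - margin),
                     numeric(1))
      if (c_i == 1 ||
          all(sqrt(rowSums(sweep(centers[seq_len(c_i - 1), , drop = FALSE],
                                 2, cand)^2)) >= min_sep)) {
        centers[c_i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("grid dims too small to place ", n_sources,
                      " well-separated sources")
  }
  radius <- 2.5  # blob sd in voxels
  maps <- matrix(0, n_sources, n_vox)
  for (c_i in seq_len(n_sources)) {
    d2 <- rowSums(sweep(coords, 2, centers[c_i, ])^2)
    m <- exp(-d2 / (2 * radius^2))
    m[m < 0.05] <- 0  # compact support
    maps[c_i, ] <- m
  }
  mixing <- matrix(rnorm(n_subjects * n_sources, mixing_mean, mixing_sd),
                   n_subjects, n_sources)
  X <- mixing %*% maps
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), 0, noise_sd), nrow(X))
  volumes <- lapply(seq_len(n_subjects), function(s)
    volume(array(X[s, ], dims), spacing))
  names(volumes) <- sprintf("sub%03d", seq_len(n_subjects))

  templates <- lapply(seq_len(n_sources), function(c_i)
    array(maps[c_i, ] > 0.3, dims))
  names(templates) <- sprintf("source%d", seq_len(n_sources))

  # label atlas: blob cores by strongest source, corner block as reference
  lab <- integer(n_vox)
  strongest <- apply(maps, 2, which.max)
  core <- apply(maps, 2, max) > 0.3
  lab[core] <- strongest[core]
  ref_label <- n_sources + 1L
  corner <- coords[, 1] <= 3 & coords[, 2] <= 3 & coords[, 3] <= 3
  lab[corner & lab == 0] <- ref_label
  names_df <- data.frame(
    label = c(seq_len(n_sources), ref_label),
    name = c(sprintf("source%d", seq_len(n_sources)), "reference"),
    stringsAsFactors = FALSE)
  atlas <- roi_atlas(array(lab, dims), names = names_df,
                     reference_label = ref_label, spacing = spacing)
  attr(maps, "dims") <- dims
  list(volumes = volumes, mixing = mixing, maps = maps,
       templates = templates, atlas = atlas, seed = seed)
}
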