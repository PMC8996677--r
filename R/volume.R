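#' 3D intensity volume
#'
#' Minimal container for a PET image: a 3D numeric grid plus voxel spacing
#' in mm. Volumes are written and read as NIfTI-1 via the RNifti package;
#' spacing is carried in `pixdim`.
#'
#' @param data numeric 3D array.
#' @param spacing voxel edge lengths in mm (3 positive reals).
#' @param mask_nan if `TRUE`, non-finite voxels are tolerated and excluded
#'   from ROI means downstream; otherwise they are an error.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), mask_nan = FALSE) {
  if (length(dim(data)) != 3) stop("volume data must be a 3D array")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive voxel edge lengths (mm)")
  storage.mode(data) <- "double"
  if (!mask_nan && any(!is.finite(data)))
    stop("volume contains non-finite voxels; use mask_nan = TRUE to mask them")
  structure(list(data = data, spacing = as.numeric(spacing),
                 mask_nan = isTRUE(mask_nan)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Read / write a volume as NIfTI-1
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param mask_nan tolerate non-finite voxels (see [volume()]).
#' @return `read_volume` returns a [volume()]; `write_volume` returns
#'   `path` invisibly. Data are stored as float64 so values round-trip
#'   exactly.
#' @export
read_volume <- function(path, mask_nan = FALSE) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  volume(as.array(img), spacing = RNifti::pixdim(img)[1:3],
         mask_nan = mask_nan)
}

#' @rdname read_volume
#' @param v a [volume()].
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  arr <- v$data
  RNifti::pixdim(arr) <- v$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path,
                     datatype = "double")
  invisible(path)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with a full-width-half-maximum given in mm;
#' the per-axis sigma in voxels is `fwhm / (2 sqrt(2 ln 2)) / spacing`,
#' so anisotropic voxels are handled per axis. Boundaries use reflect
#' padding by default, which preserves constant volumes in the interior.
#'
#' @param v a [volume()].
#' @param fwhm_mm positive full-width-half-maximum in mm.
#' @param boundary `"reflect"` (default) or `"zero"` padding.
#' @return The smoothed [volume()].
#' @export
smooth_volume <- function(v, fwhm_mm, boundary = c("reflect", "zero")) {
  stopifnot(inherits(v, "volume"))
  boundary <- match.arg(boundary)
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0) stop("fwhm_mm must be positive")
  if (any(!is.finite(v$data)))
    stop("cannot smooth a volume with non-finite voxels")
  sigmas <- fwhm_sigma(fwhm_mm) / v$spacing
  out <- v$data
  for (axis in 1:3) out <- convolve_axis(out, axis, sigmas[axis], boundary)
  volume(out, v$spacing)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm_mm full-width-half-maximum.
#' @return `fwhm_mm / (2 sqrt(2 ln 2))`.
#' @export
fwhm_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

convolve_axis <- function(arr, axis, sigma, boundary) {
  n <- dim(arr)[axis]
  radius <- ceiling(4 * sigma)
  if (radius < 1) return(arr)
  kern <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(m))
  for (k in -radius:radius) {
    src <- idx + k
    if (boundary == "reflect") {
      # reflect about the edges (symmetric half-sample style: 1,2,... <- 1- maps to 1)
      src <- ifelse(src < 1, 1 - src, src)
      src <- ifelse(src > n, 2 * n + 1 - src, src)
      src <- pmax(1L, pmin(n, src))
      out <- out + kern[k + radius + 1] * m[src, , drop = FALSE]
    } else {
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + kern[k + radius + 1] * m[src[ok], , drop = FALSE]
    }
  }
  aperm(array(out, dim(arr)[perm]), order(perm))
}

#' Intensity normalization to a reference region (SUVR)
#'
#' Divides every voxel by the mean intensity over the atlas reference
#' region (e.g., cerebellar gray matter), yielding a standardized uptake
#' value ratio image.
#'
#' @param v a [volume()].
#' @param atlas a [roi_atlas()] with `reference_label` set.
#' @return The normalized [volume()].
#' @export
compute_suvr <- function(v, atlas) {
  stopifnot(inherits(v, "volume"), inherits(atlas, "roi_atlas"))
  if (is.null(atlas$reference_label))
    stop("atlas has no reference_label for intensity normalization")
  if (!all(dim(v$data) == dim(atlas$labels)))
    stop("volume and atlas grids differ")
  ref <- v$data[atlas$labels == atlas$reference_label]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0) stop("reference region is empty")
  m <- mean(ref)
  if (m <= 0) stop("reference region mean must be positive (got ", m, ")")
  volume(v$data / m, v$spacing, mask_nan = v$mask_nan)
}
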