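#' ROI label atlas
#'
#' Integer label grid aligned with the analysis volumes: 0 is background,
#' positive labels are ROIs. One label can be designated the
#' intensity-normalization reference region (cerebellar gray matter in the
#' usual PET workflow); it is then excluded from the extracted ROI set.
#' An optional module assignment per label feeds the participation
#' coefficient.
#'
#' @param labels 3D integer array.
#' @param names data.frame with columns `label` and `name` covering every
#'   nonzero label (auto-generated when `NULL`); may carry `x`, `y`, `z`
#'   coordinates and a `module` column.
#' @param reference_label optional label of the reference region.
#' @param spacing voxel spacing in mm.
#' @return An object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, names = NULL, reference_label = NULL,
                      spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3) stop("atlas labels must be a 3D array")
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (is.null(names))
    names <- data.frame(label = present, name = sprintf("roi%03d", present),
                        stringsAsFactors = FALSE)
  if (!all(c("label", "name") %in% colnames(names)))
    stop("names table needs 'label' and 'name' columns")
  missing <- setdiff(present, names$label)
  if (length(missing))
    stop("labels present in the grid but absent from the names table: ",
         paste(missing, collapse = ", "))
  if (!is.null(reference_label)) {
    reference_label <- as.integer(reference_label)
    if (!any(labels == reference_label))
      stop("reference_label ", reference_label, " has no voxels")
  }
  structure(list(labels = labels, names = names,
                 reference_label = reference_label,
                 spacing = as.numeric(spacing)),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  n_roi <- length(setdiff(unique(as.vector(x$labels)),
                          c(0L, x$reference_label)))
  cat(sprintf("<roi_atlas> %s grid, %d ROIs%s\n",
              paste(dim(x$labels), collapse = "x"), n_roi,
              if (!is.null(x$reference_label))
                sprintf(", reference label %d", x$reference_label) else ""))
  invisible(x)
}

#' Read / write an ROI atlas
#'
#' The label grid travels as NIfTI-1 (integer datatype); the ROI metadata
#' table (label, name, optional coordinates and module) as CSV.
#'
#' @param nifti_path label volume path (`.nii`/`.nii.gz`).
#' @param names_path optional CSV path for the metadata table.
#' @param reference_label optional reference region label.
#' @return `read_atlas` returns an [roi_atlas()]; `write_atlas` returns
#'   the paths invisibly.
#' @export
read_atlas <- function(nifti_path, names_path = NULL, reference_label = NULL) {
  if (!file.exists(nifti_path)) stop("atlas file not found: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  names <- if (!is.null(names_path)) read.csv(names_path) else NULL
  roi_atlas(round(as.array(img)), names = names,
            reference_label = reference_label,
            spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_atlas
#' @param atlas an [roi_atlas()].
#' @export
write_atlas <- function(atlas, nifti_path, names_path = NULL) {
  stopifnot(inherits(atlas, "roi_atlas"))
  arr <- atlas$labels
  RNifti::pixdim(arr) <- atlas$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), nifti_path,
                     datatype = "int32")
  if (!is.null(names_path)) write.csv(atlas$names, names_path,
                                      row.names = FALSE)
  invisible(c(nifti_path, names_path))
}

#' Extract the subjects-by-ROI SUVR matrix
#'
#' For every subject volume and every atlas ROI, the unweighted mean
#' intensity over the ROI's voxels. Columns follow sorted label order; the
#' reference label, if any, is excluded. Voxels masked as non-finite (see
#' [volume()]) are dropped from the mean.
#'
#' @param volumes list of [volume()]s sharing the atlas grid.
#' @param atlas an [roi_atlas()].
#' @param group per-subject group labels.
#' @param subject_ids subject identifiers (defaults to list names).
#' @param covariates optional per-subject data.frame.
#' @return A [suvr_matrix()] with ROI names taken from the atlas table.
#' @export
extract_roi_matrix <- function(volumes, atlas, group,
                               subject_ids = names(volumes),
                               covariates = NULL) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!length(volumes)) stop("no volumes supplied")
  labels <- sort(setdiff(unique(as.vector(atlas$labels)),
                         c(0L, atlas$reference_label)))
  if (!length(labels)) stop("atlas has no ROI labels")
  lab_vec <- as.vector(atlas$labels)
  roi_idx <- lapply(labels, function(l) which(lab_vec == l))
  empty <- labels[lengths(roi_idx) == 0]
  if (length(empty)) stop("ROI label(s) without voxels: ",
                          paste(empty, collapse = ", "))
  vals <- t(vapply(volumes, function(v) {
    stopifnot(inherits(v, "volume"))
    if (!all(dim(v$data) == dim(atlas$labels)))
      stop("volume grid does not match the atlas grid")
    x <- as.vector(v$data)
    vapply(roi_idx, function(ii) {
      xi <- x[ii]
      xi <- xi[is.finite(xi)]
      if (!length(xi)) stop("ROI has only masked voxels")
      mean(xi)
    }, numeric(1))
  }, numeric(length(labels))))
  roi_names <- atlas$names$name[match(labels, atlas$names$label)]
  if (is.null(subject_ids))
    subject_ids <- sprintf("sub%03d", seq_along(volumes))
  suvr_matrix(vals, group, subject_ids, roi_names, covariates)
}
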