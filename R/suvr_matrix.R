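#' Subjects-by-ROI SUVR matrix
#'
#' Container for regional standardized uptake value ratios: one row per
#' subject, one column per ROI, with a per-subject group label and optional
#' nuisance covariates (age, sex). This is the common input of all network
#' estimation steps.
#'
#' @param values numeric matrix, subjects x ROIs; must contain no missing
#'   values.
#' @param group character or factor of length `nrow(values)`.
#' @param subject_ids character vector of subject identifiers; defaults to
#'   rownames of `values`.
#' @param roi_labels character vector of ROI names; defaults to colnames of
#'   `values`.
#' @param covariates optional data.frame of per-subject covariates (e.g.
#'   `age`, `sex`), one row per subject.
#' @return An object of class `suvr_matrix`.
#' @export
suvr_matrix <- function(values, group, subject_ids = rownames(values),
                        roi_labels = colnames(values), covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("SUVR values must be finite and non-missing")
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(n))
  if (is.null(roi_labels)) roi_labels <- sprintf("roi%03d", seq_len(p))
  if (length(subject_ids) != n) stop("subject_ids must match number of rows")
  if (length(roi_labels) != p) stop("roi_labels must match number of columns")
  if (length(group) != n) stop("group must have one label per subject")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per subject")
  }
  rownames(values) <- subject_ids
  colnames(values) <- roi_labels
  structure(list(values = values,
                 subject_ids = as.character(subject_ids),
                 roi_labels = as.character(roi_labels),
                 group = factor(group),
                 covariates = covariates),
            class = "suvr_matrix")
}

#' @export
print.suvr_matrix <- function(x, ...) {
  cat(sprintf("<suvr_matrix> %d subjects x %d ROIs\n",
              nrow(x$values), ncol(x$values)))
  cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$group),
                                 tabulate(x$group)), collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.suvr_matrix <- function(x) dim(x$values)

#' Extract the subjects of one group
#'
#' @param x a [suvr_matrix()].
#' @param group group level to keep.
#' @return A `suvr_matrix` restricted to the subjects of `group`.
#' @export
subset_group <- function(x, group) {
  stopifnot(inherits(x, "suvr_matrix"))
  keep <- x$group == group
  if (!any(keep)) stop("no subjects in group '", group, "'")
  suvr_matrix(x$values[keep, , drop = FALSE], x$group[keep],
              x$subject_ids[keep], x$roi_labels,
              if (!is.null(x$covariates)) x$covariates[keep, , drop = FALSE])
}

#' Restrict an SUVR matrix to a set of ROIs
#'
#' @param x a [suvr_matrix()].
#' @param rois character vector of ROI labels (or integer indices).
#' @return A `suvr_matrix` restricted to `rois`.
#' @export
subset_rois <- function(x, rois) {
  stopifnot(inherits(x, "suvr_matrix"))
  if (is.numeric(rois)) rois <- x$roi_labels[rois]
  if (!all(rois %in% x$roi_labels)) stop("unknown ROI label(s)")
  suvr_matrix(x$values[, rois, drop = FALSE], x$group, x$subject_ids, rois,
              x$covariates)
}

#' Write / read an SUVR table as CSV
#'
#' The on-disk layout is one row per subject with columns `subject_id`,
#' `group`, any covariates, then one column per ROI.
#'
#' @param x a [suvr_matrix()].
#' @param path file path.
#' @return `write_suvr_table` returns `path` invisibly; `read_suvr_table`
#'   returns a [suvr_matrix()].
#' @export
write_suvr_table <- function(x, path) {
  stopifnot(inherits(x, "suvr_matrix"))
  df <- data.frame(subject_id = x$subject_ids, group = as.character(x$group),
                   stringsAsFactors = FALSE)
  if (!is.null(x$covariates)) df <- cbind(df, x$covariates)
  df <- cbind(df, as.data.frame(x$values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_suvr_table
#' @param covariate_cols names of covariate columns; by default any of
#'   `age`, `sex` present in the file.
#' @export
read_suvr_table <- function(path, covariate_cols = intersect(c("age", "sex"),
                                                             names(df))) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  force(covariate_cols)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("SUVR table must have 'subject_id' and 'group' columns")
  roi_cols <- setdiff(names(df), c(need, covariate_cols))
  values <- as.matrix(df[, roi_cols, drop = FALSE])
  covs <- if (length(covariate_cols))
    df[, covariate_cols, drop = FALSE] else NULL
  suvr_matrix(values, df$group, df$subject_id, roi_cols, covs)
}
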