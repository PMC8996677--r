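#' Identify network hubs by the mean + 1 SD rule
#'
#' A node is a hub when its centrality strictly exceeds the network mean by
#' `sd_mult` sample standard deviations. The default criterion in this
#' package is degree centrality (AUC-integrated over the density sweep);
#' the participation coefficient can be supplied instead via `criterion`.
#' With a constant criterion vector nothing exceeds the mean, so no hubs
#' are returned (not an error).
#'
#' @param criterion per-node centrality values (degree or participation
#'   coefficient), length >= 3, finite.
#' @param sd_mult multiplier of the sample standard deviation (default 1).
#' @return Logical hub flag per node.
#' @export
identify_hubs <- function(criterion, sd_mult = 1) {
  criterion <- as.numeric(criterion)
  if (length(criterion) < 3) stop("need at least 3 nodes")
  if (any(!is.finite(criterion))) stop("criterion must be finite")
  criterion > mean(criterion) + sd_mult * sd(criterion)
}

#' Classify hub reorganisation between two groups
#'
#' Given hub flags in a control-like group and a target group, each ROI is
#' assigned exactly one category: `lost` (hub in control only), `preserved`
#' (hub in both), `reconfigured` (hub in target only), or `non-hub`.
#'
#' @param hubs_control,hubs_target logical hub flags, aligned.
#' @param roi_labels ROI names (defaults to indices).
#' @param criterion_control,criterion_target optional criterion values to
#'   carry into the output table.
#' @return An object of class `hub_taxonomy`: data.frame with columns
#'   `roi`, `hub_control`, `hub_target`, `category` (factor with levels
#'   lost/preserved/reconfigured/non-hub) and the criterion values; the
#'   per-category counts are attached as attribute `counts`.
#' @export
classify_hubs <- function(hubs_control, hubs_target,
                          roi_labels = seq_along(hubs_control),
                          criterion_control = NA_real_,
                          criterion_target = NA_real_) {
  if (length(hubs_control) != length(hubs_target))
    stop("hub flag vectors must be aligned")
  if (length(roi_labels) != length(hubs_control))
    stop("roi_labels must be aligned with hub flags")
  category <- ifelse(hubs_control & !hubs_target, "lost",
              ifelse(hubs_control & hubs_target, "preserved",
              ifelse(!hubs_control & hubs_target, "reconfigured", "non-hub")))
  out <- data.frame(roi = as.character(roi_labels),
                    criterion_control = criterion_control,
                    criterion_target = criterion_target,
                    hub_control = hubs_control, hub_target = hubs_target,
                    category = factor(category, levels = c(
                      "lost", "preserved", "reconfigured", "non-hub")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$category)
  class(out) <- c("hub_taxonomy", class(out))
  out
}

#' @export
print.hub_taxonomy <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<hub_taxonomy> %d ROIs: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
  NextMethod()
}

#' Hub taxonomy from two SUVR groups
#'
#' End-to-end hub comparison: estimate each group's networks across the
#' density sweep, integrate the hub criterion (degree centrality by
#' default, participation coefficient optionally) over the sweep, apply the
#' mean + 1 SD rule in each group, and classify ROIs.
#'
#' @param x_control,x_target [suvr_matrix()] objects with the same ROIs.
#' @param densities density sweep (see [build_adjacency_series()]).
#' @param criterion `"degree"` (default) or `"participation"`.
#' @param sd_mult hub threshold multiplier.
#' @param seed seed for module detection (participation criterion only).
#' @return A `hub_taxonomy` (see [classify_hubs()]).
#' @export
hub_taxonomy <- function(x_control, x_target,
                         densities = seq(0.10, 0.40, by = 0.02),
                         criterion = c("degree", "participation"),
                         sd_mult = 1, seed = 1L) {
  criterion <- match.arg(criterion)
  crit_of <- function(x) {
    ser <- build_adjacency_series(x, densities)
    if (criterion == "degree") {
      metrics_over_series(ser)$degree_auc
    } else {
      pc <- vapply(ser$adjacency, function(A)
        participation_coefficient(A, detect_modules(A, seed)),
        numeric(length(ser$roi_labels)))
      apply(pc, 1, metric_auc, densities = ser$densities)
    }
  }
  cc <- crit_of(x_control)
  ct <- crit_of(x_target)
  labels <- if (inherits(x_control, "suvr_matrix")) x_control$roi_labels
            else names(cc)
  classify_hubs(identify_hubs(cc, sd_mult), identify_hubs(ct, sd_mult),
                roi_labels = labels,
                criterion_control = as.numeric(cc),
                criterion_target = as.numeric(ct))
}
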