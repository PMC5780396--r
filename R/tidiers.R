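#' Tidy a detection result into one row per object
#'
#' @param x A `bspim_detections`.
#' @param ... Unused.
#' @return A tibble with label, centroid (um), voxel count and peak
#'   activity.
#' @export
tidy.bspim_detections <- function(x, ...) x$objects

#' One-row summary of a detection result
#'
#' @param x A `bspim_detections`.
#' @param ... Unused.
#' @export
glance.bspim_detections <- function(x, ...) {
  tibble::tibble(count = x$count,
                 total_voxels = sum(x$objects$voxels),
                 threshold = x$params$threshold,
                 min_voxels = x$params$min_voxels,
                 connectivity = x$params$connectivity)
}

#' Coefficient table of a recovery regression
#'
#' @param x A `bspim_recovery_fit`.
#' @param ... Unused.
#' @export
tidy.bspim_recovery_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a recovery regression
#'
#' @param x A `bspim_recovery_fit`.
#' @param ... Unused.
#' @export
glance.bspim_recovery_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, spearman_rho = x$spearman_rho,
                 spearman_p = x$spearman_p, n_points = x$n_points,
                 per = x$per, through_origin = x$through_origin)
}

#' Per-pair folds of an S/N comparison
#'
#' @param x A `bspim_sn_folds`.
#' @param ... Unused.
#' @export
tidy.bspim_sn_folds <- function(x, ...) x$folds

#' One-row summary of an S/N fold comparison
#'
#' @param x A `bspim_sn_folds`.
#' @param ... Unused.
#' @export
glance.bspim_sn_folds <- function(x, ...) {
  tibble::tibble(mean_fold = x$mean_fold, se_fold = x$se_fold,
                 min_fold = x$min_fold, max_fold = x$max_fold,
                 n_used = x$n_used, n_excluded = x$n_excluded)
}
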