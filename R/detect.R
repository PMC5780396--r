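#' Parameters of the 3D detection pipeline
#'
#' The segmentation settings used to count regions of high biospeckle
#' activity: boxcar background radius, 3D Gaussian sigma, the 8-bit
#' brightness threshold, the minimum component size in voxels, and the 3D
#' neighbourhood definition. Defaults are the published pipeline settings
#' (2 mm boxcar, 80 um sigma, threshold 40, minimum 50 voxels) with the
#' conventional 26-voxel connectivity.
#'
#' @param boxcar_radius_um Boxcar background radius, micrometres.
#' @param gaussian_sigma_um 3D Gaussian sigma, micrometres (isotropic in
#'   physical units).
#' @param threshold 8-bit brightness threshold in `[0, 255]`.
#' @param min_voxels Minimum voxel count for a component to be kept (>= 1).
#' @param connectivity 3D adjacency: 6 (faces), 18 (+edges) or 26 (+corners).
#' @return A `bspim_detection_params` list.
#' @export
detection_params <- function(boxcar_radius_um = 2000,
                             gaussian_sigma_um = 80,
                             threshold = 40,
                             min_voxels = 50,
                             connectivity = 26) {
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  }
  if (min_voxels < 1) stop("`min_voxels` must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  structure(list(boxcar_radius_um = boxcar_radius_um,
                 gaussian_sigma_um = gaussian_sigma_um,
                 threshold = threshold,
                 min_voxels = as.integer(min_voxels),
                 connectivity = as.integer(connectivity)),
            class = "bspim_detection_params")
}

#' Count high-activity objects in a filtered volume
#'
#' Binarizes the volume at `threshold` (values greater than or equal pass),
#' labels 3D connected components at the configured connectivity, discards
#' components smaller than `min_voxels`, and reports each surviving object's
#' centroid (in micrometres, unweighted mean of member voxel centers with
#' the origin at the first voxel's center), voxel count and peak activity.
#'
#' @param volume A filtered `gd_volume` (8-bit value range).
#' @param params A [detection_params()].
#' @return A `bspim_detections`: list with `count`, an `objects` tibble and
#'   the parameters used. An empty result (count 0) is valid.
#' @export
count_objects <- function(volume, params = detection_params()) {
  mask <- unclass(volume) >= params$threshold
  lab <- cpp_label3d(mask, dim(volume), params$connectivity)
  sizes <- tabulate(lab)
  keep <- which(sizes >= params$min_voxels)
  v <- attr(volume, "voxel_size_um")
  if (is.null(v)) v <- c(1, 1, 1)
  if (length(keep) == 0) {
    objects <- tibble::tibble(label = integer(), x_um = numeric(),
                              y_um = numeric(), z_um = numeric(),
                              voxels = integer(), peak_activity = numeric())
  } else {
    d <- dim(volume)
    idx <- which(lab %in% keep)
    new_lab <- match(lab[idx], keep)  # keep is ascending = scan order
    i <- (idx - 1) %% d[1]
    j <- ((idx - 1) %/% d[1]) %% d[2]
    k <- (idx - 1) %/% (d[1] * d[2])
    sums <- rowsum(cbind(i, j, k), new_lab)
    sizes_kept <- as.integer(sizes[keep])
    vals <- unclass(volume)[idx]
    objects <- tibble::tibble(
      label = seq_along(keep),
      x_um = sums[, 1] / sizes_kept * v[1],
      y_um = sums[, 2] / sizes_kept * v[2],
      z_um = sums[, 3] / sizes_kept * v[3],
      voxels = sizes_kept,
      peak_activity = vapply(split(vals, new_lab), max, 0, USE.NAMES = FALSE))
  }
  structure(list(count = nrow(objects), objects = objects, params = params),
            class = "bspim_detections")
}

#' @export
print.bspim_detections <- function(x, ...) {
  cat(sprintf("<bspim detections> %d object(s)\n", x$count))
  if (x$count > 0) print(x$objects)
  invisible(x)
}

#' Run the detection tail on a raw GD volume
#'
#' The published filtering/counting sequence applied after GD
#' reconstruction: global 8-bit conversion, boxcar background subtraction,
#' 3D Gaussian smoothing, then threshold + size-filtered 3D component
#' counting. Summary statistics of every stage are recorded in the `stages`
#' attribute of the result.
#'
#' @param volume A raw-state `gd_volume`.
#' @param params A [detection_params()].
#' @return A `bspim_detections`.
#' @export
detect_from_volume <- function(volume, params = detection_params()) {
  stage_stats <- function(name, vol) {
    tibble::tibble(stage = name, min = min(vol), mean = mean(vol),
                   max = max(vol))
  }
  v8 <- rescale_to_8bit(volume)
  vb <- subtract_boxcar(v8, params$boxcar_radius_um)
  vg <- gaussian_smooth(vb, params$gaussian_sigma_um)
  res <- count_objects(vg, params)
  attr(res, "stages") <- dplyr::bind_rows(
    stage_stats("gd_raw", volume), stage_stats("8bit", v8),
    stage_stats("boxcar", vb), stage_stats("gaussian", vg))
  res
}

#' Detect live nematodes in a BSPIM scan
#'
#' Full automatic detection: GD reconstruction of every position, 8-bit
#' conversion, boxcar and Gaussian filtering, and thresholded 3D object
#' counting. Live animals decorrelate the speckle and appear as bright
#' connected regions spanning the overlapping sheet positions; static
#' material (soil matrix, heat-killed nematodes, saturated roots) carries no
#' temporal signal and is removed by the filters and threshold.
#'
#' @param scan A `bspim_scan`.
#' @param params A [detection_params()].
#' @param lag_policy,max_lag GD lag policy (see
#'   [generalized_differences()]).
#' @param crop Optional physical crop (see [reconstruct_gd_volume()]).
#' @return A `bspim_detections` with per-stage summary statistics in the
#'   `stages` attribute.
#' @export
detect_nematodes <- function(scan, params = detection_params(),
                             lag_policy = c("all", "max_lag"),
                             max_lag = NULL, crop = NULL) {
  lag_policy <- match.arg(lag_policy)
  vol <- reconstruct_gd_volume(scan, lag_policy = lag_policy,
                               max_lag = max_lag, crop = crop)
  detect_from_volume(vol, params)
}
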