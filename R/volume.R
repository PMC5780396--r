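new_gd_volume <- function(vol, voxel_size_um, state = "raw",
                          rescale_range = NULL) {
  structure(vol, class = c("gd_volume", "array"),
            voxel_size_um = voxel_size_um, state = state,
            rescale_range = rescale_range)
}

#' @export
print.gd_volume <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_size_um")
  cat(sprintf(
    "<GD volume> %d x %d x %d voxels (%g x %g x %g um), %s, [%g, %g]\n",
    d[1], d[2], d[3], v[1], v[2], v[3], attr(x, "state"), min(x), max(x)))
  invisible(x)
}

#' Assemble per-position GD images into a calibrated activity volume
#'
#' Computes the generalized-differences image of every stack in a scan and
#' stacks them along z on the acquisition's voxel grid (in-plane pixel size
#' by the stage increment). The result is in raw floating-point GD units;
#' [rescale_to_8bit()] is the first step of the detection pipeline.
#'
#' @param scan A `bspim_scan` (from [simulate_scan()] or [read_scan()]).
#' @param lag_policy,max_lag Passed to [generalized_differences()].
#' @param crop Optional physical crop, a list with any of `x_um`, `y_um`,
#'   `z_um`, each a `c(lo, hi)` range in micrometres (region-of-interest
#'   selection, e.g. a mixing layer or soil column).
#' @return A raw-state `gd_volume`.
#' @export
reconstruct_gd_volume <- function(scan, lag_policy = c("all", "max_lag"),
                                  max_lag = NULL, crop = NULL) {
  lag_policy <- match.arg(lag_policy)
  stacks <- scan$stacks
  if (length(stacks) < 1) stop("scan has no positions", call. = FALSE)
  zs <- vapply(stacks, function(s) attr(s, "z_position_um"), 0)
  if (length(zs) > 1) {
    dz <- diff(zs)
    if (any(abs(dz - dz[1]) > 1e-6 * abs(dz[1])) || dz[1] <= 0) {
      stop("stage positions must be uniformly spaced and increasing in z",
           call. = FALSE)
    }
    dz <- dz[1]
  } else {
    dz <- scan$acquisition$z_increment_um
  }
  px <- attr(stacks[[1]], "pixel_size_um")
  if (is.null(px)) px <- 1
  d <- dim(stacks[[1]])
  vol <- array(0, c(d[1], d[2], length(stacks)))
  for (i in seq_along(stacks)) {
    vol[, , i] <- generalized_differences(stacks[[i]], lag_policy = lag_policy,
                                          max_lag = max_lag)
  }
  out <- new_gd_volume(vol, voxel_size_um = c(px, px, dz), state = "raw")
  if (!is.null(crop)) out <- crop_volume(out, crop)
  out
}

#' Crop a GD volume to a physical region of interest
#'
#' @param volume A `gd_volume`.
#' @param crop List with any of `x_um`, `y_um`, `z_um` ranges (`c(lo, hi)`).
#' @return The cropped `gd_volume`.
#' @export
crop_volume <- function(volume, crop) {
  v <- attr(volume, "voxel_size_um")
  d <- dim(volume)
  sel <- function(range_um, n, step) {
    if (is.null(range_um)) return(seq_len(n))
    ctr <- (seq_len(n) - 0.5) * step
    which(ctr >= range_um[1] & ctr <= range_um[2])
  }
  ix <- sel(crop$x_um, d[1], v[1])
  iy <- sel(crop$y_um, d[2], v[2])
  iz <- sel(crop$z_um, d[3], v[3])
  if (!length(ix) || !length(iy) || !length(iz)) {
    stop("crop region contains no voxels", call. = FALSE)
  }
  new_gd_volume(unclass(volume)[ix, iy, iz, drop = FALSE],
                voxel_size_um = v, state = attr(volume, "state"))
}

#' Convert a raw GD volume to 8-bit
#'
#' Linear min-max mapping of the whole volume onto `[0, 255]`, rounded half
#' up. The scaling is global (one affine map for the entire volume), so
#' relative activity is preserved across z and no per-slice contrast jumps
#' can fabricate structure. A constant volume maps to all zeros.
#'
#' @param volume A raw-state `gd_volume`.
#' @return An 8-bit-state `gd_volume`; the original `(min, max)` is kept in
#'   the `rescale_range` attribute.
#' @export
rescale_to_8bit <- function(volume) {
  if (!identical(attr(volume, "state"), "raw")) {
    stop("`rescale_to_8bit()` expects a raw-state volume", call. = FALSE)
  }
  lo <- min(volume); hi <- max(volume)
  v <- unclass(volume)
  out <- if (hi > lo) floor((v - lo) / (hi - lo) * 255 + 0.5) else v * 0
  new_gd_volume(out, voxel_size_um = attr(volume, "voxel_size_um"),
                state = "8bit", rescale_range = c(lo, hi))
}

#' Subtract long-range background with a boxcar average
#'
#' Removes slowly varying illumination/background trends by subtracting the
#' local boxcar (moving-average) mean of radius `radius_um`, applied in 2D
#' within each z slice (long-range variation arises in the image plane), with
#' reflect padding; negative residuals are clipped to zero. Set `axes =
#' "3d"` to average over z as well.
#'
#' @param volume An 8-bit-state `gd_volume`.
#' @param radius_um Boxcar radius in micrometres (default 2 mm).
#' @param axes `"2d"` (per slice, default) or `"3d"`.
#' @return A `gd_volume` of non-negative residuals (still 8-bit state).
#' @export
subtract_boxcar <- function(volume, radius_um = 2000, axes = c("2d", "3d")) {
  axes <- match.arg(axes)
  if (!identical(attr(volume, "state"), "8bit")) {
    stop("`subtract_boxcar()` expects an 8-bit-state volume", call. = FALSE)
  }
  v <- attr(volume, "voxel_size_um")
  rx <- round(radius_um / v[1]); ry <- round(radius_um / v[2])
  if (rx < 1 || ry < 1) {
    warning("boxcar radius below one pixel; using the minimum 3-px window")
    rx <- max(rx, 1L); ry <- max(ry, 1L)
  }
  d <- dim(volume)
  m <- cpp_boxcar_mean(as.numeric(volume), d, as.integer(rx), as.integer(ry))
  if (axes == "3d") {
    rz <- max(1L, round(radius_um / v[3]))
    nz <- d[3]
    m2 <- array(m, d)
    zpad <- function(i) { i <- ifelse(i < 1, 1 - i, i)
                          ifelse(i > nz, 2 * nz + 1 - i, i) }
    acc <- array(0, d)
    for (dz in -rz:rz) acc <- acc + m2[, , zpad(seq_len(nz) + dz)]
    m <- acc / (2 * rz + 1)
  }
  out <- unclass(volume) - array(m, d)
  out[out < 0] <- 0
  new_gd_volume(out, voxel_size_um = v, state = "8bit",
                rescale_range = attr(volume, "rescale_range"))
}

#' Smooth a volume with an anisotropic-voxel-aware 3D Gaussian
#'
#' Separable Gaussian blur with the sigma given in physical units and
#' converted per axis to voxel units (so an 80 um sigma is 5 px in-plane at
#' 16 um/px but only 0.64 voxels along a 125 um z step), reflect padding.
#' `sigma_um = 0` returns the input unchanged.
#'
#' @param volume A `gd_volume`.
#' @param sigma_um Isotropic physical sigma in micrometres (default 80), or
#'   a length-3 vector of per-axis sigmas.
#' @return The smoothed `gd_volume`.
#' @export
gaussian_smooth <- function(volume, sigma_um = 80) {
  v <- attr(volume, "voxel_size_um")
  s <- rep(sigma_um, length.out = 3) / v
  if (all(s <= 0)) return(volume)
  out <- cpp_gauss3d(as.numeric(volume), dim(volume), s[1], s[2], s[3])
  new_gd_volume(array(out, dim(volume)), voxel_size_um = v,
                state = attr(volume, "state"),
                rescale_range = attr(volume, "rescale_range"))
}
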