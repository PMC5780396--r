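#' Acquisition settings for a biospeckle light-sheet scan
#'
#' Bundles the parameters of a BSPIM volume acquisition: at each position of
#' the motorized stage a time-lapse of speckle frames is recorded, the stage
#' moves by `z_increment_um` and the sequence repeats. The defaults follow the
#' automated-detection protocol: 64 frames at 10 fps per position, 80
#' positions at 125 um increments through a 1 cm cuvette, and a thick (1 mm)
#' light sheet so that successive optical sections overlap and no animal falls
#' between sections. A 30 um sheet is the thin, rendering-quality alternative.
#'
#' @param frames_per_position Number of frames recorded at each stage
#'   position (>= 2).
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param n_positions Number of stage positions along z.
#' @param z_increment_um Stage step between positions, in micrometres.
#' @param sheet_thickness_um Light-sheet thickness in micrometres. Any
#'   positive value is accepted; 1000 (detection mode) and 30 (rendering
#'   mode) are the two standard settings.
#' @param settle_pause_s Pause after each stage move before acquisition, in
#'   seconds (metadata only; the simulator assumes the sample has settled).
#' @param exposure_scale Camera gain: digital numbers (DN) corresponding to
#'   the mean intensity of fully developed background speckle.
#' @param bit_depth Sensor bit depth (8 or 16).
#' @param read_noise_sd Additive read noise, standard deviation in DN.
#' @param grain_sigma_px Spatial speckle grain: sigma (pixels) of the
#'   Gaussian low-pass applied to the complex field and its innovations.
#'   `0` disables spatial correlation.
#'
#' @return An object of class `bspim_acq` (a named list).
#' @examples
#' acquisition_config()
#' acquisition_config(sheet_thickness_um = 30, n_positions = 40)
#' @export
acquisition_config <- function(frames_per_position = 64,
                               frame_rate_hz = 10,
                               n_positions = 80,
                               z_increment_um = 125,
                               sheet_thickness_um = 1000,
                               settle_pause_s = 0.4,
                               exposure_scale = 60,
                               bit_depth = 8,
                               read_noise_sd = 1,
                               grain_sigma_px = 2) {
  if (frames_per_position < 2) {
    stop("`frames_per_position` must be at least 2", call. = FALSE)
  }
  if (z_increment_um <= 0) stop("`z_increment_um` must be > 0", call. = FALSE)
  if (sheet_thickness_um <= 0) {
    stop("`sheet_thickness_um` must be > 0", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  if (n_positions < 1) stop("`n_positions` must be >= 1", call. = FALSE)
  if (read_noise_sd < 0) stop("`read_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      frames_per_position = as.integer(frames_per_position),
      frame_rate_hz = frame_rate_hz,
      n_positions = as.integer(n_positions),
      z_increment_um = z_increment_um,
      sheet_thickness_um = sheet_thickness_um,
      settle_pause_s = settle_pause_s,
      exposure_scale = exposure_scale,
      bit_depth = as.integer(bit_depth),
      read_noise_sd = read_noise_sd,
      grain_sigma_px = grain_sigma_px
    ),
    class = "bspim_acq"
  )
}

#' @export
print.bspim_acq <- function(x, ...) {
  cat("<bspim acquisition>\n")
  cat(sprintf("  %d frames @ %g fps at each of %d positions\n",
              x$frames_per_position, x$frame_rate_hz, x$n_positions))
  cat(sprintf("  z step %g um, sheet %g um, %d-bit, read noise %g DN\n",
              x$z_increment_um, x$sheet_thickness_um, x$bit_depth,
              x$read_noise_sd))
  invisible(x)
}

max_dn <- function(acq) as.integer(2^acq$bit_depth - 1)
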