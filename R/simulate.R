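#' Advance a complex speckle field by one frame interval
#'
#' Reference implementation of the temporal decorrelation model: each pixel
#' of the complex scattered-field amplitude follows a stationary AR(1)
#' process, `E' = rho * E + sqrt(1 - rho^2) * eta`, with `eta` a fresh
#' circular complex Gaussian variate of the same marginal variance. `rho = 1`
#' leaves the field (and hence the speckle pattern) unchanged; `rho = 0`
#' fully decorrelates it between frames. The lag-k autocorrelation of the
#' field is `rho^k` and the marginal intensity distribution stays negative
#' exponential (fully developed speckle), which is what makes the model a
#' faithful source for generalized-differences analysis.
#'
#' Uses R's global RNG; seed with [set.seed()] for reproducibility. The
#' compiled scan simulator implements the same process (plus optional spatial
#' speckle grain) with its own seeded generator.
#'
#' @param field Complex matrix: the current field amplitudes.
#' @param rho Decorrelation coefficient(s) in `[0, 1]`; scalar or a matrix
#'   conformable with `field`.
#' @return A complex matrix of the same shape.
#' @examples
#' set.seed(1)
#' f <- init_field(c(32, 32))
#' f2 <- evolve_field(f, rho = 0.8)
#' @export
evolve_field <- function(field, rho) {
  if (any(rho < 0 | rho > 1)) {
    stop("`rho` must lie in [0, 1]", call. = FALSE)
  }
  n <- length(field)
  eta <- complex(real = rnorm(n, sd = sqrt(0.5)),
                 imaginary = rnorm(n, sd = sqrt(0.5)))
  out <- rho * field + sqrt(1 - rho^2) * eta
  dim(out) <- dim(field)
  out
}

#' Draw an initial fully developed speckle field
#'
#' Independent circular complex Gaussian amplitudes with unit mean intensity,
#' the standard model for fully developed speckle.
#'
#' @param shape Integer vector `(nx, ny)`.
#' @return A complex matrix.
#' @export
init_field <- function(shape) {
  n <- prod(shape)
  matrix(complex(real = rnorm(n, sd = sqrt(0.5)),
                 imaginary = rnorm(n, sd = sqrt(0.5))),
         shape[1], shape[2])
}

#' Render a camera frame from a speckle field
#'
#' Converts field amplitudes to detected intensity `|E|^2`, applies the
#' camera gain and optional per-pixel brightness, pushes saturated regions
#' (e.g. roots imaged at raised exposure) far above full scale, adds Gaussian
#' read noise, then clips to the sensor range and quantizes. Saturated pixels
#' therefore read the maximum digital number in every frame and carry no
#' temporal signal.
#'
#' Uses R's global RNG for the read noise.
#'
#' @param field Complex matrix of field amplitudes.
#' @param acq An [acquisition_config()].
#' @param brightness Scalar or matrix of static brightness factors.
#' @param saturate Optional logical matrix of sensor-saturated pixels.
#' @return An integer matrix in `[0, 2^bit_depth - 1]`.
#' @export
render_frame <- function(field, acq, brightness = 1, saturate = NULL) {
  mv <- max_dn(acq)
  I <- (Re(field)^2 + Im(field)^2) * acq$exposure_scale * brightness
  if (!is.null(saturate)) {
    if (!identical(dim(saturate), dim(field))) {
      stop("`saturate` must match the field shape", call. = FALSE)
    }
    I[saturate] <- 10 * mv + 1000
  }
  if (acq$read_noise_sd > 0) {
    I <- I + rnorm(length(I), sd = acq$read_noise_sd)
  }
  out <- floor(I + 0.5)
  out[out < 0] <- 0
  out[out > mv] <- mv
  storage.mode(out) <- "integer"
  dim(out) <- dim(field)
  out
}

# per-position stream seed: distinct, reproducible, < 2^53
position_seed <- function(seed, index) {
  as.numeric(seed) * 2^20 + as.numeric(index)
}

#' Simulate the frame stack recorded at one stage position
#'
#' Runs the compiled speckle engine for a single light-sheet position of a
#' scene: the sheet (of the configured thickness) selects the slab of the
#' scene it illuminates, static matrix and clutter produce a frozen speckle
#' pattern, live nematodes decorrelate it over time, roots saturate the
#' sensor, and read noise plus quantization give the recorded frames.
#'
#' @param scene A [make_scene()] scene.
#' @param acq An [acquisition_config()].
#' @param index Stage position index (1-based).
#' @param seed Scan seed; each position derives its own stream from it.
#' @param return_frames `TRUE` (materialize the stack), `FALSE`, or
#'   `"first"` (keep only the first frame, e.g. as the brightfield image of
#'   the position). The values drawn are identical in all modes, so the
#'   streamed GD matches the GD of the materialized stack exactly.
#' @param return_gd Also accumulate the generalized-differences image in a
#'   streaming pass (no stack is materialized when `return_frames = FALSE`).
#' @param max_lag Lag policy for the streamed GD (`0` = all pairs).
#' @return A list with `frames` (an `nx * ny * n_frames` integer array of
#'   class `bspim_stack`, or `NULL`), `frame1` (integer matrix or `NULL`)
#'   and `gd` (matrix or `NULL`).
#' @export
simulate_position <- function(scene, acq, index, seed = scene$seed,
                              return_frames = TRUE, return_gd = FALSE,
                              max_lag = 0) {
  z <- position_z_um(scene, index)
  maps <- slab_maps(scene, z, acq$sheet_thickness_um)
  frames_mode <- if (identical(return_frames, "first")) 2L
                 else if (isTRUE(return_frames)) 1L else 0L
  res <- cpp_sim_position(
    maps$rho, maps$brightness, maps$saturate, maps$obj,
    acq$frames_per_position, acq$exposure_scale, acq$read_noise_sd,
    max_dn(acq), acq$grain_sigma_px, scene$clutter_sd,
    scene$clutter_scale_px, position_seed(seed, index),
    frames_mode, return_gd, as.integer(max_lag)
  )
  frames <- NULL
  if (!is.null(res$frames)) {
    frames <- res$frames
    dim(frames) <- c(scene$grid_shape[1], scene$grid_shape[2],
                     acq$frames_per_position)
    frames <- new_stack(frames, position_index = index, z_position_um = z,
                        pixel_size_um = scene$voxel_size_xy_um)
  }
  list(frames = frames, frame1 = res$frame1, gd = res$gd)
}

new_stack <- function(frames, position_index, z_position_um, pixel_size_um) {
  structure(frames, class = c("bspim_stack", class(frames)),
            position_index = position_index, z_position_um = z_position_um,
            pixel_size_um = pixel_size_um)
}

#' Simulate a full BSPIM volume scan
#'
#' Generates one frame stack per stage position, exactly as the instrument
#' would record them. With a 1 mm sheet stepped at 125 um, a nematode's
#' activity footprint appears in about 8 consecutive stacks; the overlapping
#' sections are later merged by 3D connected-component counting. The output
#' is bit-reproducible from `(scene, acq, seed)`.
#'
#' @inheritParams simulate_position
#' @param seed Integer scan seed (defaults to the scene seed).
#' @return A `bspim_scan`: list of per-position stacks plus the acquisition
#'   settings and the ground-truth scene.
#' @examples
#' sc <- make_scene(1, grid_shape = c(64, 64, 8), seed = 2)
#' scan <- simulate_scan(sc, acquisition_config(n_positions = 8,
#'                                              frames_per_position = 8))
#' @export
simulate_scan <- function(scene, acq = acquisition_config(),
                          seed = scene$seed) {
  stacks <- lapply(seq_len(acq$n_positions), function(i) {
    simulate_position(scene, acq, i, seed = seed,
                      return_frames = TRUE, return_gd = FALSE)$frames
  })
  structure(list(stacks = stacks, acquisition = acq, truth = scene,
                 seed = seed),
            class = "bspim_scan")
}

#' @export
print.bspim_scan <- function(x, ...) {
  d <- dim(x$stacks[[1]])
  cat(sprintf("<bspim scan> %d positions, %d x %d px, %d frames each\n",
              length(x$stacks), d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate a scan and reduce it to its GD activity volume
#'
#' Memory-lean path used by the recovery experiments: each position's stack
#' is simulated and immediately collapsed to its generalized-differences
#' image, so the full 4D frame set is never held at once. Produces, by
#' construction, the same volume as `simulate_scan()` followed by
#' [reconstruct_gd_volume()] with the same seed.
#'
#' @inheritParams simulate_scan
#' @param max_lag Lag policy (`0` = all-pairs sum).
#' @return A raw-float `gd_volume`.
#' @export
simulate_gd_volume <- function(scene, acq = acquisition_config(),
                               seed = scene$seed, max_lag = 0) {
  nx <- scene$grid_shape[1]; ny <- scene$grid_shape[2]
  vol <- array(0, c(nx, ny, acq$n_positions))
  for (i in seq_len(acq$n_positions)) {
    vol[, , i] <- simulate_position(scene, acq, i, seed = seed,
                                    return_frames = FALSE, return_gd = TRUE,
                                    max_lag = max_lag)$gd
  }
  new_gd_volume(vol,
                voxel_size_um = c(scene$voxel_size_xy_um,
                                  scene$voxel_size_xy_um,
                                  acq$z_increment_um),
                state = "raw")
}
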