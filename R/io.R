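#' Write a BSPIM scan to disk
#'
#' Writes one multi-page grayscale TIFF per stage position
#' (`pos_0000.tif`, `pos_0001.tif`, ...), a plain-text `manifest.txt` with
#' the calibration (pixel size, z step, frame rate, frame count, sheet
#' thickness, bit depth, seed), and - when the scan carries a ground-truth
#' scene - a `truth.csv` table of nematode positions and states.
#'
#' @param scan A `bspim_scan`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acq <- scan$acquisition
  mv <- max_dn(acq)
  for (i in seq_along(scan$stacks)) {
    st <- scan$stacks[[i]]
    pages <- lapply(seq_len(dim(st)[3]), function(t) {
      unclass(st)[, , t] / mv
    })
    tiff::writeTIFF(pages, file.path(dir, sprintf("pos_%04d.tif", i - 1)),
                    bits.per.sample = acq$bit_depth)
  }
  manifest <- c(
    pixel_size_um = attr(scan$stacks[[1]], "pixel_size_um"),
    z_step_um = acq$z_increment_um,
    frame_rate_hz = acq$frame_rate_hz,
    frames_per_position = acq$frames_per_position,
    n_positions = length(scan$stacks),
    sheet_thickness_um = acq$sheet_thickness_um,
    settle_pause_s = acq$settle_pause_s,
    exposure_scale = acq$exposure_scale,
    bit_depth = acq$bit_depth,
    read_noise_sd = acq$read_noise_sd,
    seed = if (is.null(scan$seed)) NA else scan$seed
  )
  writeLines(paste0(names(manifest), ": ", unname(manifest)),
             file.path(dir, "manifest.txt"))
  if (!is.null(scan$truth)) {
    write.csv(scan$truth$nematodes, file.path(dir, "truth.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), "")
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  out <- as.list(vals)
  for (k in names(out)) {
    num <- suppressWarnings(as.numeric(out[[k]]))
    if (!is.na(num)) out[[k]] <- num
  }
  out
}

#' Read a BSPIM scan from disk
#'
#' Loads the per-position multi-page TIFFs and manifest written by
#' [write_scan()] (or by an acquisition rig following the same layout) back
#' into a `bspim_scan`. Calibration comes from the manifest and can be
#' overridden; an override is reported with a message. Inconsistent frame
#' counts, mixed bit depths or unreadable files raise descriptive errors.
#'
#' @param dir Scan directory.
#' @param pixel_size_um,z_step_um Optional calibration overrides.
#' @return A `bspim_scan` (with `truth = NULL`; the ground-truth table, if
#'   present, is attached as the `truth_table` attribute).
#' @export
read_scan <- function(dir, pixel_size_um = NULL, z_step_um = NULL) {
  man_path <- file.path(dir, "manifest.txt")
  if (!file.exists(man_path)) {
    stop(sprintf("no manifest.txt found in '%s'", dir), call. = FALSE)
  }
  man <- read_manifest(man_path)
  if (!is.null(pixel_size_um)) {
    message(sprintf("pixel size override: %g um (manifest: %g um)",
                    pixel_size_um, man$pixel_size_um))
    man$pixel_size_um <- pixel_size_um
  }
  if (!is.null(z_step_um)) {
    message(sprintf("z step override: %g um (manifest: %g um)",
                    z_step_um, man$z_step_um))
    man$z_step_um <- z_step_um
  }
  files <- sort(list.files(dir, pattern = "^pos_[0-9]+\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0) {
    stop(sprintf("no position TIFFs (pos_*.tif) found in '%s'", dir),
         call. = FALSE)
  }
  stacks <- vector("list", length(files))
  frame_counts <- integer(length(files))
  bit_depths <- integer(length(files))
  for (i in seq_along(files)) {
    pages <- tryCatch(
      tiff::readTIFF(files[i], all = TRUE, as.is = TRUE, info = TRUE),
      error = function(e) {
        stop(sprintf("failed to read '%s': %s", files[i], conditionMessage(e)),
             call. = FALSE)
      })
    if (!is.list(pages)) pages <- list(pages)
    frame_counts[i] <- length(pages)
    bit_depths[i] <- attr(pages[[1]], "bits.per.sample")
    arr <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
    storage.mode(arr) <- "integer"
    stacks[[i]] <- new_stack(arr, position_index = i,
                             z_position_um = (i - 0.5) * man$z_step_um,
                             pixel_size_um = man$pixel_size_um)
  }
  if (length(unique(frame_counts)) > 1) {
    stop("inconsistent frame counts across position TIFFs", call. = FALSE)
  }
  if (length(unique(bit_depths)) > 1) {
    stop("mixed bit depths across position TIFFs", call. = FALSE)
  }
  acq <- acquisition_config(
    frames_per_position = frame_counts[1],
    frame_rate_hz = man$frame_rate_hz %||% 10,
    n_positions = length(files),
    z_increment_um = man$z_step_um,
    sheet_thickness_um = man$sheet_thickness_um %||% 1000,
    settle_pause_s = man$settle_pause_s %||% 0.4,
    exposure_scale = man$exposure_scale %||% 60,
    bit_depth = bit_depths[1],
    read_noise_sd = man$read_noise_sd %||% 1
  )
  truth_tab <- NULL
  if (file.exists(file.path(dir, "truth.csv"))) {
    truth_tab <- tibble::as_tibble(read.csv(file.path(dir, "truth.csv")))
  }
  structure(list(stacks = stacks, acquisition = acq, truth = NULL,
                 seed = man$seed),
            class = "bspim_scan") |>
    structure(truth_table = truth_tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a GD image as a 32-bit float TIFF
#'
#' GD values are stored in normalized units `GD / (n_pairs * max_DN)` (which
#' lie in `[0, 1]` by construction) because float TIFF storage is defined on
#' that range; the scale is returned and also written to a plain-text
#' sidecar so the raw values can be recovered exactly to float precision.
#'
#' @param gd A `gd_image`.
#' @param path Output path.
#' @param max_dn Full-scale digital number of the source frames (255 for
#'   8-bit).
#' @return The scale factor (raw = stored * scale), invisibly.
#' @export
write_gd_tiff <- function(gd, path, max_dn = 255) {
  scale <- attr(gd, "n_pairs") * max_dn
  if (isTRUE(attr(gd, "normalized"))) scale <- max_dn
  tiff::writeTIFF(unclass(gd) / scale, path, bits.per.sample = 32L)
  writeLines(c(sprintf("scale: %.10g", scale),
               sprintf("n_frames: %d", attr(gd, "n_frames")),
               sprintf("lag_policy: %s", attr(gd, "lag_policy"))),
             paste0(path, ".txt"))
  invisible(scale)
}

#' Read back a float GD TIFF written by [write_gd_tiff()]
#'
#' @param path TIFF path (the `.txt` sidecar must sit next to it).
#' @return A numeric matrix of raw GD values.
#' @export
read_gd_tiff <- function(path) {
  side <- read_manifest(paste0(path, ".txt"))
  tiff::readTIFF(path) * side$scale
}
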