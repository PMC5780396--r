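#' Read intensities along a straight transect of an image
#'
#' Samples an image along the rasterized segment from `start` to `end` (pixel
#' coordinates, `c(row, col)`), the way line profiles are drawn from the edge
#' of a sample, through the medium, across a detected object. The sample
#' nearest `signal_point` is flagged as the signal pixel for the
#' signal-to-noise computation; `signal_point` must lie on the segment to
#' within half a pixel.
#'
#' @param image Numeric matrix (a raw frame or a `gd_image`).
#' @param start,end Segment endpoints, `c(row, col)`, inside the image.
#' @param signal_point Location of the object on the segment, `c(row, col)`.
#' @return A `bspim_transect`: list with `samples`, `signal_index`, and the
#'   sampled pixel coordinates.
#' @export
extract_transect <- function(image, start, end, signal_point) {
  dm <- dim(image)
  inb <- function(p) p[1] >= 1 && p[1] <= dm[1] && p[2] >= 1 && p[2] <= dm[2]
  if (!inb(start) || !inb(end)) {
    stop("transect endpoints must lie inside the image", call. = FALSE)
  }
  n <- max(abs(end[1] - start[1]), abs(end[2] - start[2])) + 1
  if (n < 3) {
    stop("degenerate transect: fewer than 3 samples", call. = FALSE)
  }
  rows <- round(seq(start[1], end[1], length.out = n))
  cols <- round(seq(start[2], end[2], length.out = n))
  if (pt_seg_dist(as.numeric(signal_point), as.numeric(start),
                  as.numeric(end)) > 0.5 + 1e-9) {
    stop("`signal_point` must lie on the transect (within half a pixel)",
         call. = FALSE)
  }
  d2 <- (rows - signal_point[1])^2 + (cols - signal_point[2])^2
  structure(list(samples = as.numeric(image[cbind(rows, cols)]),
                 signal_index = which.min(d2),
                 rows = rows, cols = cols,
                 start = start, end = end),
            class = "bspim_transect")
}

#' @export
print.bspim_transect <- function(x, ...) {
  cat(sprintf("<transect> %d samples, signal at index %d (value %g)\n",
              length(x$samples), x$signal_index,
              x$samples[x$signal_index]))
  invisible(x)
}

#' Transect signal-to-noise ratio
#'
#' The contrast metric `SN = (I_s - <I>) / sigma`, where `I_s` is the
#' intensity at the detected object, and `<I>` and `sigma` are the mean and
#' sample standard deviation (n - 1 denominator) of *all* samples along the
#' transect, signal pixel included. SN is invariant to adding a constant to
#' the whole transect and to positive rescaling.
#'
#' @param transect A [extract_transect()] result, or a list/numeric vector of
#'   samples together with `signal_index`.
#' @param signal_index Index of the signal sample when `transect` is a bare
#'   numeric vector.
#' @return A `bspim_sn`: list with `sn`, `i_s`, `mean` and `sd`.
#' @examples
#' signal_to_noise(c(0, 0, 0, 100, 0), signal_index = 4)
#' @export
signal_to_noise <- function(transect, signal_index = NULL) {
  if (is.numeric(transect)) {
    if (is.null(signal_index)) {
      stop("`signal_index` is required for a bare sample vector",
           call. = FALSE)
    }
    samples <- as.numeric(transect)
  } else {
    samples <- transect$samples
    signal_index <- transect$signal_index
  }
  if (length(samples) < 3) {
    stop("a transect needs at least 3 samples", call. = FALSE)
  }
  if (signal_index < 1 || signal_index > length(samples)) {
    stop("`signal_index` out of range", call. = FALSE)
  }
  s <- sd(samples)
  if (!is.finite(s) || s == 0) {
    stop("signal-to-noise is undefined: zero variance along the transect",
         call. = FALSE)
  }
  m <- mean(samples)
  structure(list(sn = (samples[signal_index] - m) / s,
                 i_s = samples[signal_index], mean = m, sd = s),
            class = "bspim_sn")
}

#' @export
print.bspim_sn <- function(x, ...) {
  cat(sprintf("<transect S/N> SN = %.3f (I_s = %g, mean = %.3f, sd = %.3f)\n",
              x$sn, x$i_s, x$mean, x$sd))
  invisible(x)
}
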