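#' Generalized-differences biospeckle activity map
#'
#' Collapses a time-lapse speckle stack to a single activity image by
#' summing, at every pixel, the absolute intensity differences between
#' frames: `GD = sum_i sum_j |I_(i+j) - I_i|`. Under the default all-pairs
#' policy the double sum runs over every unordered frame pair, so GD measures
#' the total temporal variation of the pixel over the stack; static pixels
#' (including sensor-saturated ones) score exactly zero. A `max_lag` policy
#' restricts the time increment `j` to at most `k` frames, the lag-limited
#' variant sometimes used in biospeckle work.
#'
#' Accumulation is exact: with 64 frames of 8-bit input the largest possible
#' value is 2016 * 255, far inside double (and 32-bit) integer range.
#'
#' @param stack A `bspim_stack` or a numeric array with frames along the
#'   third dimension (at least 2 frames).
#' @param lag_policy `"all"` (all unordered pairs, the default) or
#'   `"max_lag"`.
#' @param max_lag Maximum time increment `j` when `lag_policy = "max_lag"`.
#' @param normalize Divide by the number of pairs summed, for comparability
#'   across stacks of different length. The raw sum is the default.
#' @return A `gd_image`: numeric matrix of non-negative activity values with
#'   attributes `lag_policy`, `n_frames`, `n_pairs` and (when available)
#'   `position_index`, `z_position_um`, `pixel_size_um`.
#' @examples
#' st <- array(c(0, 3, 0), c(1, 1, 3))
#' generalized_differences(st)  # |3-0| + |0-0| + |0-3| = 6
#' @export
generalized_differences <- function(stack,
                                    lag_policy = c("all", "max_lag"),
                                    max_lag = NULL, normalize = FALSE) {
  lag_policy <- match.arg(lag_policy)
  frames <- unclass(stack)
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3) {
    stop("`stack` must be an array with frames along the third dimension",
         call. = FALSE)
  }
  nf <- dim(frames)[3]
  if (nf < 2) stop("a stack needs at least 2 frames", call. = FALSE)
  if (any(frames < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (lag_policy == "max_lag") {
    if (is.null(max_lag) || max_lag < 1) {
      stop("`max_lag` must be >= 1 under the max_lag policy", call. = FALSE)
    }
    k <- as.integer(min(max_lag, nf - 1))
  } else {
    k <- 0L
  }
  gd <- cpp_gd_stack(as.numeric(frames), dim(frames), k)
  n_pairs <- if (k == 0) nf * (nf - 1) / 2 else sum(nf - seq_len(k))
  if (normalize) gd <- gd / n_pairs
  structure(gd,
            class = c("gd_image", "matrix", "array"),
            lag_policy = lag_policy,
            max_lag = if (k > 0) k else NULL,
            n_frames = nf, n_pairs = n_pairs, normalized = normalize,
            position_index = attr(stack, "position_index"),
            z_position_um = attr(stack, "z_position_um"),
            pixel_size_um = attr(stack, "pixel_size_um"))
}

#' @export
print.gd_image <- function(x, ...) {
  cat(sprintf(
    "<GD image> %d x %d px, %d frames, policy %s%s, range [%g, %g]\n",
    nrow(x), ncol(x), attr(x, "n_frames"), attr(x, "lag_policy"),
    if (!is.null(attr(x, "max_lag"))) paste0("(", attr(x, "max_lag"), ")")
    else "",
    min(x), max(x)))
  invisible(x)
}
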