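#' Plot a count-recovery table
#'
#' Detected versus inserted nematode numbers: per-count means with standard
#' deviation bars, the fitted regression line and the identity line.
#'
#' @param object A `bspim_recovery` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bspim_recovery <- function(object, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$true_count),
    mean_detected = mean(.data$detected_count),
    sd_detected = sd(.data$detected_count), .groups = "drop")
  fit <- summarize_recovery(object, per = "mean")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$true_count,
                                  y = .data$mean_detected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_detected - .data$sd_detected,
      ymax = .data$mean_detected + .data$sd_detected), width = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "nematodes inserted",
      y = "nematodes detected (mean ± SD)",
      title = sprintf("Count recovery (R² = %.4f)", fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot one z slice of a GD volume
#'
#' @param object A `gd_volume`.
#' @param z Slice index (default: the slice with the highest total
#'   activity).
#' @param ... Unused.
#' @return A ggplot raster of the activity map.
#' @export
autoplot.gd_volume <- function(object, z = NULL, ...) {
  v <- unclass(object)
  if (is.null(z)) z <- which.max(apply(v, 3, sum))
  sl <- v[, , z]
  d <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  d$value <- as.vector(sl)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$x,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "GD") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("GD activity, slice %d", z),
                  x = "y (px)", y = "x (px)") +
    ggplot2::theme_minimal()
}

#' Plot a transect profile
#'
#' @param object A `bspim_transect`.
#' @param ... Unused.
#' @return A ggplot line profile with the signal sample marked.
#' @export
autoplot.bspim_transect <- function(object, ...) {
  d <- tibble::tibble(index = seq_along(object$samples),
                      value = object$samples)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$signal_index,
                        linetype = "dotted", colour = "red") +
    ggplot2::labs(x = "sample", y = "intensity") +
    ggplot2::theme_minimal()
}
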