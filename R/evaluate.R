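#' Count-recovery experiment on simulated cuvette scans
#'
#' For every requested true count and replicate, builds a seeded scene,
#' simulates the BSPIM acquisition and runs the full detection pipeline,
#' yielding a table of inserted versus detected nematode numbers - the
#' simulator surrogate of inserting 0-20 animals into fluorimeter cuvettes
#' and counting them automatically. `medium = "soil"` adds strong static
#' background heterogeneity (refractive-index clutter of soil + colloid),
#' which is temporally constant and must be suppressed by the pipeline.
#'
#' @param counts Vector of true (inserted) nematode counts.
#' @param replicates Replicates per count.
#' @param medium `"clean"` (colloid only) or `"soil"` (heterogeneous).
#' @param seed Experiment seed; each run derives a distinct sub-seed.
#' @param acq An [acquisition_config()].
#' @param params A [detection_params()].
#' @param alive_fraction Fraction of live animals per scene (0 reproduces
#'   the heat-killed control series).
#' @param scene_args Extra arguments passed on to [make_scene()].
#' @param quiet Suppress per-run progress messages.
#' @return A `bspim_recovery` tibble with columns `true_count`, `replicate`,
#'   `detected_count`, `seed`; the medium is kept as an attribute.
#' @export
run_recovery_experiment <- function(counts = 0:20, replicates = 3,
                                    medium = c("clean", "soil"),
                                    seed = 1,
                                    acq = acquisition_config(),
                                    params = detection_params(),
                                    alive_fraction = 1,
                                    scene_args = list(),
                                    quiet = TRUE) {
  medium <- match.arg(medium)
  if (any(counts < 0)) stop("`counts` must be non-negative", call. = FALSE)
  clutter <- if (medium == "soil") 0.8 else 0
  runs <- expand.grid(replicate = seq_len(replicates), true_count = counts)
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run_seed <- as.integer(seed) + 7919L * i
    args <- modifyList(
      list(n_nematodes = runs$true_count[i],
           alive_fraction = alive_fraction,
           clutter_sd = clutter,
           grid_shape = c(256, 256, acq$n_positions),
           z_step_um = acq$z_increment_um,
           seed = run_seed),
      scene_args)
    scene <- do.call(make_scene, args)
    vol <- simulate_gd_volume(scene, acq, seed = run_seed)
    det <- detect_from_volume(vol, params)
    if (!quiet) {
      message(sprintf("count %d rep %d: detected %d",
                      runs$true_count[i], runs$replicate[i], det$count))
    }
    out[[i]] <- tibble::tibble(true_count = runs$true_count[i],
                               replicate = runs$replicate[i],
                               detected_count = det$count,
                               seed = run_seed)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bspim_recovery", class(res))
  attr(res, "medium") <- medium
  attr(res, "alive_fraction") <- alive_fraction
  res
}

#' Regression summary of a count-recovery table
#'
#' Ordinary least squares of detected on inserted counts plus a Spearman
#' rank-order correlation. `per = "mean"` regresses the mean detected count
#' per inserted count (the way recovery results are usually plotted, points
#' with SD bars); `per = "row"` uses every replicate row. A through-origin
#' fit is available since recovery lines are often anchored at zero.
#'
#' For the free-intercept fit, R-squared equals the squared Pearson
#' correlation of the two columns. If the detected counts have zero variance
#' the line explains nothing and R-squared is defined as 0.
#'
#' @param table A `bspim_recovery` tibble (or any data frame with
#'   `true_count` and `detected_count` columns).
#' @param per `"mean"` or `"row"`.
#' @param through_origin Force the regression through the origin.
#' @return A `bspim_recovery_fit`: list with `r_squared`, `slope`,
#'   `intercept`, `spearman_rho`, `spearman_p`, `n_points` and the
#'   underlying `lm` fit.
#' @export
summarize_recovery <- function(table, per = c("mean", "row"),
                               through_origin = FALSE) {
  per <- match.arg(per)
  if (length(unique(table$true_count)) < 3) {
    stop("at least 3 distinct true counts are required", call. = FALSE)
  }
  d <- if (per == "mean") {
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(table),
                                     .data$true_count),
                     detected_count = mean(.data$detected_count),
                     .groups = "drop")
  } else {
    tibble::as_tibble(table)[c("true_count", "detected_count")]
  }
  if (sd(d$true_count) == 0) {
    stop("degenerate design: no variance in `true_count`", call. = FALSE)
  }
  fit <- if (through_origin) {
    lm(detected_count ~ 0 + true_count, data = d)
  } else {
    lm(detected_count ~ true_count, data = d)
  }
  r2 <- if (sd(d$detected_count) == 0) {
    0
  } else if (through_origin) {
    suppressWarnings(summary(fit)$r.squared)
  } else {
    cor(d$true_count, d$detected_count)^2
  }
  n <- nrow(d)
  ties <- anyDuplicated(d$true_count) > 0 ||
    anyDuplicated(d$detected_count) > 0
  sp <- if (sd(d$detected_count) == 0) {
    list(estimate = NA_real_, p.value = NA_real_)
  } else {
    suppressWarnings(cor.test(d$true_count, d$detected_count,
                              method = "spearman",
                              exact = (n <= 10 && !ties)))
  }
  structure(list(r_squared = r2,
                 slope = unname(coef(fit)[["true_count"]]),
                 intercept = if (through_origin) 0
                             else unname(coef(fit)[["(Intercept)"]]),
                 spearman_rho = unname(sp$estimate),
                 spearman_p = sp$p.value,
                 n_points = n, per = per, through_origin = through_origin,
                 fit = fit, data = d),
            class = "bspim_recovery_fit")
}

#' @export
print.bspim_recovery_fit <- function(x, ...) {
  cat(sprintf(
    "<recovery fit> R^2 = %.4f, slope = %.3f, intercept = %.3f\n",
    x$r_squared, x$slope, x$intercept))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g), n = %d (%s%s)\n",
              x$spearman_rho, x$spearman_p, x$n_points, x$per,
              if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Brightfield versus GD signal-to-noise experiment
#'
#' Simulates single-nematode scenes over a range of static clutter levels
#' and measures, for each, the transect signal-to-noise ratio on a raw
#' brightfield speckle frame and on the GD activity image of the same
#' position, along the same transect through the animal. This is the
#' simulator surrogate of profiling grey values across a sample: static
#' scatter dominates the brightfield profile but cancels in GD, which is
#' where the contrast gain of biospeckle imaging comes from.
#'
#' The nematode is oriented in-plane, perpendicular to the transect, and the
#' transect spans the full image width through the animal's centroid.
#'
#' @param n_scenes Number of scenes (clutter levels are spread over
#'   `clutter_range`).
#' @param clutter_range Range of log-sd clutter levels to span.
#' @param seed Batch seed.
#' @param image_px Image size (square), pixels.
#' @param acq An [acquisition_config()]; only the per-position settings are
#'   used (a single position per scene is simulated).
#' @param brightness Nematode brightness factor in brightfield.
#' @param rho_live Nematode decorrelation coefficient.
#' @return A tibble with one row per scene: `scene`, `clutter_sd`,
#'   `sn_brightfield`, `sn_gd`.
#' @export
run_sn_experiment <- function(n_scenes = 12,
                              clutter_range = c(0.5, 2.5),
                              seed = 1,
                              image_px = 1024,
                              acq = acquisition_config(),
                              brightness = 1.5,
                              rho_live = 0.7) {
  stopifnot(n_scenes >= 1)
  clutter <- seq(clutter_range[1], clutter_range[2], length.out = n_scenes)
  nz <- 8L
  out <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    scene_seed <- as.integer(seed) + 7919L * s
    scene <- make_scene(1, grid_shape = c(image_px, image_px, nz),
                        clutter_sd = clutter[s],
                        rho_live = rho_live, brightness = brightness,
                        max_tilt_deg = 0, seed = scene_seed)
    # body along image rows (x); the row transect runs along columns (y),
    # crossing the animal perpendicular to its axis
    scene$nematodes$ux <- 1
    scene$nematodes$uy <- 0
    scene$nematodes$uz <- 0
    w <- scene$nematodes
    pos <- which.min(abs((seq_len(nz) - 0.5) * scene$z_step_um - w$z_um))
    sim <- simulate_position(scene, acq, pos, seed = scene_seed,
                             return_frames = "first", return_gd = TRUE)
    row <- max(1, min(image_px, round(w$x_um / scene$voxel_size_xy_um + 0.5)))
    tr_args <- list(start = c(row, 1), end = c(row, image_px),
                    signal_point = c(row,
                                     max(1, min(image_px,
                                       round(w$y_um /
                                               scene$voxel_size_xy_um +
                                               0.5)))))
    bf <- sim$frame1
    sn_bf <- signal_to_noise(do.call(extract_transect, c(list(bf), tr_args)))
    sn_gd <- signal_to_noise(do.call(extract_transect,
                                     c(list(sim$gd), tr_args)))
    out[[s]] <- tibble::tibble(scene = s, clutter_sd = clutter[s],
                               sn_brightfield = sn_bf$sn, sn_gd = sn_gd$sn)
  }
  dplyr::bind_rows(out)
}

#' Fold change of the transect signal-to-noise ratio
#'
#' Per-pair fold improvement `SN_GD / SN_brightfield` for matched transects,
#' with pairs whose brightfield SN is not positive excluded (the fold is
#' undefined there) under a logged warning. Returns the per-pair folds plus
#' mean, standard error, min and max.
#'
#' @param pairs A data frame with columns `sn_brightfield` and `sn_gd` (as
#'   returned by [run_sn_experiment()]).
#' @return A `bspim_sn_folds`: list with `folds` (tibble), `mean_fold`,
#'   `se_fold`, `min_fold`, `max_fold`, `n_used`, `n_excluded`.
#' @export
sn_fold_change <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) {
    return(structure(list(folds = tibble::tibble(sn_brightfield = numeric(),
                                                 sn_gd = numeric(),
                                                 fold = numeric()),
                          mean_fold = NA_real_, se_fold = NA_real_,
                          min_fold = NA_real_, max_fold = NA_real_,
                          n_used = 0L, n_excluded = 0L),
                     class = "bspim_sn_folds"))
  }
  bad <- pairs$sn_brightfield <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d pair(s) with non-positive brightfield SN excluded (fold undefined)",
      sum(bad)))
  }
  ok <- pairs[!bad, , drop = FALSE]
  folds <- ok$sn_gd / ok$sn_brightfield
  structure(list(
    folds = dplyr::mutate(ok, fold = folds),
    mean_fold = if (length(folds)) mean(folds) else NA_real_,
    se_fold = if (length(folds) > 1) sd(folds) / sqrt(length(folds))
              else NA_real_,
    min_fold = if (length(folds)) min(folds) else NA_real_,
    max_fold = if (length(folds)) max(folds) else NA_real_,
    n_used = length(folds), n_excluded = sum(bad)),
    class = "bspim_sn_folds")
}

#' @export
print.bspim_sn_folds <- function(x, ...) {
  cat(sprintf(
    "<S/N fold change> n = %d (%d excluded): mean %.1f (SE %.1f), max %.1f\n",
    x$n_used, x$n_excluded, x$mean_fold, x$se_fold, x$max_fold))
  invisible(x)
}
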