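# Count-recovery analysis and S/N fold comparison

test_that("summarize_recovery reproduces hand-computed OLS", {
  tab <- tibble::tibble(true_count = c(0, 5, 10, 20),
                        detected_count = c(0, 4, 9, 19),
                        replicate = 1)
  fit <- summarize_recovery(tab, per = "row")
  # closed-form OLS oracle on the four points
  x <- tab$true_count; y <- tab$detected_count
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  r2 <- cor(x, y)^2
  expect_equal(fit$slope, slope)
  expect_equal(fit$intercept, intercept)
  expect_equal(fit$r_squared, r2)
  expect_equal(fit$r_squared, 44100 / 44187.5)  # frozen from the oracle
  # single-regressor identity: R^2 = squared Pearson correlation
  expect_equal(fit$r_squared, cor(x, y)^2)
})

test_that("summarize_recovery handles perfect and degenerate recovery", {
  tab <- tibble::tibble(true_count = rep(0:10, each = 3),
                        detected_count = rep(0:10, each = 3),
                        replicate = rep(1:3, 11))
  fit <- summarize_recovery(tab)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$spearman_rho, 1)
  expect_lt(fit$spearman_p, 0.001)

  flat <- tibble::tibble(true_count = 0:5, detected_count = 3, replicate = 1)
  expect_equal(summarize_recovery(flat)$r_squared, 0)

  expect_error(summarize_recovery(
    tibble::tibble(true_count = c(1, 1, 2), detected_count = c(1, 1, 2))),
    "3 distinct")

  # through-origin mode
  fo <- summarize_recovery(tab, through_origin = TRUE)
  expect_equal(fo$slope, 1)
  expect_equal(fo$intercept, 0)
})

test_that("per-mean regression averages replicates first", {
  tab <- tibble::tibble(true_count = rep(c(0, 5, 10), each = 2),
                        detected_count = c(0, 0, 4, 6, 9, 11),
                        replicate = rep(1:2, 3))
  fm <- summarize_recovery(tab, per = "mean")
  expect_equal(fm$n_points, 3)
  expect_equal(fm$r_squared, 1)  # means are exactly 0, 5, 10
  fr <- summarize_recovery(tab, per = "row")
  expect_equal(fr$n_points, 6)
  expect_lt(fr$r_squared, 1)
})

test_that("recovery experiment is deterministic and exact on empty scenes", {
  acq <- acquisition_config(frames_per_position = 8, n_positions = 6)
  args <- list(counts = c(0), replicates = 3, seed = 2, acq = acq,
               scene_args = list(grid_shape = c(64, 64, 6)))
  t1 <- do.call(run_recovery_experiment, args)
  expect_equal(t1$detected_count, c(0, 0, 0))
  t2 <- do.call(run_recovery_experiment, args)
  expect_identical(t1, t2)
})

test_that("small simulated sweeps recover the inserted counts", {
  acq <- acquisition_config(n_positions = 16)
  tab <- run_recovery_experiment(counts = c(0, 2, 4), replicates = 1,
                                 seed = 6, acq = acq,
                                 scene_args = list(
                                   grid_shape = c(128, 128, 16),
                                   length_range_um = c(150, 350)))
  expect_equal(tab$detected_count, tab$true_count)
  fit <- summarize_recovery(tab)
  expect_equal(fit$r_squared, 1)
})

test_that("sn_fold_change summarizes matched pairs and excludes bad ones", {
  pairs <- tibble::tibble(sn_brightfield = c(2, 4, 7),
                          sn_gd = c(2, 4, 7))
  fc <- sn_fold_change(pairs)
  expect_equal(fc$folds$fold, c(1, 1, 1))
  expect_equal(fc$max_fold, 1)

  pairs2 <- tibble::tibble(sn_brightfield = c(7, -1, 2),
                           sn_gd = c(156, 50, 80))
  expect_warning(fc2 <- sn_fold_change(pairs2), "excluded")
  expect_equal(fc2$n_used, 2)
  expect_equal(fc2$n_excluded, 1)
  expect_equal(fc2$max_fold, 40)
  expect_equal(fc2$folds$fold[1], 156 / 7, tolerance = 1e-12)

  empty <- sn_fold_change(tibble::tibble(sn_brightfield = numeric(),
                                         sn_gd = numeric()))
  expect_equal(empty$n_used, 0)
  expect_true(is.na(empty$max_fold))
})

test_that("the S/N experiment returns matched transect pairs", {
  sn <- run_sn_experiment(n_scenes = 3, seed = 4, image_px = 256,
                          clutter_range = c(0.6, 1.0))
  expect_equal(nrow(sn), 3)
  expect_true(all(is.finite(sn$sn_gd)))
  # GD strongly beats brightfield contrast on these clutter scenes
  expect_gt(median(sn$sn_gd), median(sn$sn_brightfield))
})

test_that("tidiers return well-formed tibbles", {
  tab <- tibble::tibble(true_count = rep(0:4, each = 2),
                        detected_count = rep(0:4, each = 2),
                        replicate = rep(1:2, 5))
  fit <- summarize_recovery(tab)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$r_squared, 1)

  v <- array(0, c(12, 12, 6)); v[2:5, 2:5, 2:5] <- 255
  det <- count_objects(as_volume(v))
  expect_equal(nrow(tidy(det)), 1)
  expect_equal(glance(det)$count, 1)
})

test_that("autoplot methods build ggplot objects", {
  tab <- run_recovery_experiment(counts = c(0, 1, 2), replicates = 2,
                                 seed = 8,
                                 acq = acquisition_config(
                                   frames_per_position = 8,
                                   n_positions = 6),
                                 scene_args = list(
                                   grid_shape = c(64, 64, 6),
                                   length_range_um = c(100, 200)))
  expect_s3_class(autoplot(tab), "ggplot")
  v <- as_volume(array(runif(64), c(4, 4, 4)))
  expect_s3_class(autoplot(v), "ggplot")
  tr <- extract_transect(matrix(1:100, 10, 10), c(2, 1), c(2, 10), c(2, 5))
  expect_s3_class(autoplot(tr), "ggplot")
})
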