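# Synthetic dynamic-speckle scene generation and field evolution

test_that("scene placement handles the empty case and is seed-reproducible", {
  s0 <- tiny_scene(0)
  expect_equal(nrow(s0$nematodes), 0)

  s1 <- make_scene(20, grid_shape = c(256, 256, 80), seed = 1)
  s2 <- make_scene(20, grid_shape = c(256, 256, 80), seed = 1)
  expect_identical(s1$nematodes, s2$nematodes)
  s3 <- make_scene(20, grid_shape = c(256, 256, 80), seed = 2)
  expect_false(identical(s1$nematodes, s3$nematodes))
})

test_that("alive_fraction controls the decorrelation assignment", {
  s <- tiny_scene(5, alive_fraction = 0, rho_bg = 1)
  expect_true(all(s$nematodes$rho == 1))
  expect_true(all(!s$nematodes$alive))

  s <- tiny_scene(5, alive_fraction = 1, rho_live = 0.6)
  expect_true(all(s$nematodes$rho == 0.6))

  s <- tiny_scene(10, nx = 224, alive_fraction = 0.5)
  expect_equal(sum(s$nematodes$alive), 5)
})

test_that("placement respects the in-plane separation or fails loudly", {
  s <- make_scene(8, grid_shape = c(256, 256, 16), min_separation_um = 400,
                  seed = 3)
  w <- s$nematodes
  for (a in seq_len(nrow(w) - 1)) {
    for (b in (a + 1):nrow(w)) {
      pa <- c(w$x_um[a], w$y_um[a]); ua <- c(w$ux[a], w$uy[a])
      pb <- c(w$x_um[b], w$y_um[b]); ub <- c(w$ux[b], w$uy[b])
      d <- bspim:::seg2_dist(pa - ua * w$length_um[a] / 2,
                             pa + ua * w$length_um[a] / 2,
                             pb - ub * w$length_um[b] / 2,
                             pb + ub * w$length_um[b] / 2)
      expect_gte(d, 400)
    }
  }
  # a grid too small for the requested count names the violated constraint
  expect_error(make_scene(40, grid_shape = c(48, 48, 8), seed = 1),
               "separation|too small")
})

test_that("nematode geometry is validated against the size envelope", {
  expect_error(tiny_scene(1, length_range_um = c(10, 100)), "envelope")
  expect_error(tiny_scene(1, width_um = 60), "width")
  expect_error(tiny_scene(1, rho_live = 1.3), "\\[0, 1\\]")
})

test_that("evolve_field is an AR(1): identity at rho 1, renewal at rho 0", {
  set.seed(42)
  f <- init_field(c(64, 64))
  expect_identical(evolve_field(f, 1), f)

  f0 <- evolve_field(f, 0)
  r <- abs(cor(c(Re(f)), c(Re(f0))))
  expect_lt(r, 0.05)
  expect_error(evolve_field(f, 1.2), "\\[0, 1\\]")
})

test_that("field autocorrelation decays as rho^k", {
  # lag-k complex autocorrelation over 1e4 pixels, 50 evolution steps
  set.seed(7)
  rho <- 0.8
  f <- init_field(c(100, 100))
  steps <- vector("list", 51)
  steps[[1]] <- f
  for (t in 2:51) steps[[t]] <- evolve_field(steps[[t - 1]], rho)
  est_lag <- function(k) {
    num <- 0; den <- 0
    for (t in seq_len(51 - k)) {
      num <- num + Re(mean(steps[[t + k]] * Conj(steps[[t]])))
      den <- den + mean(Mod(steps[[t]])^2)
    }
    num / den
  }
  expect_lt(abs(est_lag(1) - rho), 0.02)
  expect_lt(abs(est_lag(3) - rho^3), 0.03)
  expect_lt(abs(est_lag(5) - rho^5), 0.03)
})

test_that("render_frame saturates roots, clips, and respects zero exposure", {
  set.seed(1)
  acq <- acquisition_config(read_noise_sd = 0)
  f <- init_field(c(32, 32))
  sat <- matrix(FALSE, 32, 32); sat[5:10, 5:10] <- TRUE
  fr <- render_frame(f, acq, saturate = sat)
  expect_true(all(fr[sat] == 255))
  expect_true(all(fr >= 0 & fr <= 255))

  acq0 <- acquisition_config(exposure_scale = 0, read_noise_sd = 0)
  expect_true(all(render_frame(f, acq0) == 0))
})

test_that("unsaturated static speckle follows the negative-exponential law", {
  # fully developed speckle: contrast sd/mean = 1; checked on > 1e5 pixels
  sc <- make_scene(0, grid_shape = c(352, 352, 2), seed = 11)
  acq <- acquisition_config(frames_per_position = 2, n_positions = 2,
                            bit_depth = 16, read_noise_sd = 0,
                            exposure_scale = 2000)
  fr <- simulate_position(sc, acq, 1)$frames[, , 1]
  expect_gt(length(fr), 1e5)
  contrast <- sd(fr) / mean(fr)
  expect_lt(abs(contrast - 1), 0.05)
  # quantile check against the exponential distribution
  expect_lt(abs(median(fr) / mean(fr) - log(2)), 0.02)
})

test_that("per-pixel intensity statistics are stationary in time", {
  sc <- make_scene(0, grid_shape = c(128, 128, 2), seed = 12)
  acq <- acquisition_config(frames_per_position = 64, n_positions = 2)
  st <- simulate_position(sc, acq, 1)$frames
  ks <- suppressWarnings(ks.test(c(st[, , 1]), c(st[, , 64])))
  expect_gt(ks$p.value, 0.01)
})

test_that("a 1 mm sheet stepped at 125 um sees one nematode 8 times", {
  sc <- make_scene(1, grid_shape = c(96, 96, 40), seed = 21,
                   wriggle_um = 0, max_tilt_deg = 0)
  # thin in z, centred between two sheet positions: ceil(1000/125) = 8 slabs
  sc$nematodes$z_um <- 2500
  acq <- acquisition_config(n_positions = 40, frames_per_position = 8,
                            sheet_thickness_um = 1000, z_increment_um = 125)
  vol <- simulate_gd_volume(sc, acq, seed = 21)
  noise_floor <- 8 * (8 - 1) / 2 * 4  # well above any read-noise GD
  active <- which(apply(unclass(vol), 3, max) > noise_floor)
  expect_equal(length(active), ceiling(1000 / 125))
  expect_true(all(diff(active) == 1))
})

test_that("a static scene without read noise yields identical frames", {
  sc <- make_scene(0, grid_shape = c(64, 64, 4), rho_bg = 1, seed = 31)
  acq <- acquisition_config(frames_per_position = 8, n_positions = 4,
                            read_noise_sd = 0)
  scan <- simulate_scan(sc, acq, seed = 31)
  for (st in scan$stacks) {
    expect_true(all(st == as.vector(st[, , 1])))
  }
})

test_that("simulation is bit-reproducible from the seed", {
  sc <- tiny_scene(2, nx = 64, nz = 6, seed = 9)
  acq <- acquisition_config(frames_per_position = 8, n_positions = 6)
  s1 <- simulate_scan(sc, acq, seed = 9)
  s2 <- simulate_scan(sc, acq, seed = 9)
  expect_identical(s1$stacks, s2$stacks)
  s3 <- simulate_scan(sc, acq, seed = 10)
  expect_false(identical(s1$stacks, s3$stacks))
})

test_that("streamed GD equals GD of the materialized frames", {
  sc <- tiny_scene(2, nx = 64, nz = 6, seed = 13, clutter_sd = 0.5)
  acq <- acquisition_config(frames_per_position = 12, n_positions = 6)
  scan <- simulate_scan(sc, acq, seed = 13)
  v1 <- reconstruct_gd_volume(scan)
  v2 <- simulate_gd_volume(sc, acq, seed = 13)
  expect_identical(unclass(v1), unclass(v2))
})

test_that("expected temporal variation increases as rho decreases", {
  # source-level live/dead separability over a rho grid
  mean_gd <- vapply(c(1, 0.75, 0.5, 0.25, 0), function(r) {
    sc <- make_scene(0, grid_shape = c(80, 80, 2), rho_bg = r, seed = 17)
    acq <- acquisition_config(frames_per_position = 16, n_positions = 2,
                              read_noise_sd = 0)
    mean(simulate_position(sc, acq, 1, return_frames = FALSE,
                           return_gd = TRUE)$gd)
  }, 0)
  expect_true(all(diff(mean_gd) > 0))
})
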