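# Volume assembly, filtering and 3D object counting

test_that("reconstruct_gd_volume stacks GD images on the voxel grid", {
  sc <- tiny_scene(0, nx = 32, nz = 5, seed = 1)
  acq <- acquisition_config(frames_per_position = 6, n_positions = 5)
  scan <- simulate_scan(sc, acq, seed = 1)
  vol <- reconstruct_gd_volume(scan)
  expect_equal(dim(vol), c(32, 32, 5))
  expect_equal(attr(vol, "voxel_size_um"), c(16, 16, 125))
  expect_identical(attr(vol, "state"), "raw")

  # single position: a depth-1 volume equal to its own GD image
  scan1 <- simulate_scan(sc, acquisition_config(frames_per_position = 6,
                                                n_positions = 1), seed = 1)
  v1 <- reconstruct_gd_volume(scan1)
  expect_equal(v1[, , 1], unclass(generalized_differences(scan1$stacks[[1]])),
               ignore_attr = TRUE)

  # all-static, noise-free scan maps to an all-zero volume
  acq0 <- acquisition_config(frames_per_position = 6, n_positions = 5,
                             read_noise_sd = 0)
  expect_true(all(unclass(reconstruct_gd_volume(
    simulate_scan(sc, acq0, seed = 1))) == 0))

  # non-uniform z spacing is rejected
  bad <- simulate_scan(sc, acq, seed = 1)
  attr(bad$stacks[[3]], "z_position_um") <- 9999
  expect_error(reconstruct_gd_volume(bad), "uniform")
})

test_that("rescale_to_8bit applies a global half-up min-max map", {
  v <- as_volume(array(c(0, 510, 255, 100), c(2, 2, 1)), state = "raw")
  r <- rescale_to_8bit(v)
  expect_equal(r[1, 1, 1], 0)
  expect_equal(r[2, 1, 1], 255)
  expect_equal(r[1, 2, 1], 128)  # 127.5 rounds half-up to 128
  expect_identical(attr(r, "state"), "8bit")

  # constant volumes map to zero, endpoints always hit 0 and 255
  expect_true(all(rescale_to_8bit(as_volume(array(7, c(3, 3, 2)),
                                            state = "raw")) == 0))
  set.seed(5)
  r2 <- rescale_to_8bit(as_volume(array(runif(60, 3, 9), c(5, 4, 3)),
                                  state = "raw"))
  expect_equal(min(r2), 0)
  expect_equal(max(r2), 255)
  expect_error(rescale_to_8bit(r2), "raw-state")
})

test_that("boxcar subtraction removes flat and slowly varying background", {
  const <- as_volume(array(100, c(40, 40, 2)))
  expect_true(all(subtract_boxcar(const, radius_um = 160) == 0))

  # single bright voxel keeps most of its value
  v <- array(0, c(41, 41, 1)); v[21, 21, 1] <- 200
  r <- subtract_boxcar(as_volume(v), radius_um = 160)  # 10 px radius
  expect_equal(r[21, 21, 1], 200 - 200 / 21^2, tolerance = 1e-10)

  # a slow 1D ramp: brute-force windowed-mean oracle, and zero residual
  # wherever the window lies fully inside the volume
  ramp_line <- seq(0, 100, length.out = 60)
  ramp <- as_volume(array(rep(ramp_line, 60), c(60, 60, 1)))
  res <- subtract_boxcar(ramp, radius_um = 160)  # 10 px radius
  refl <- function(i, n) ifelse(i < 1, -i + 1, ifelse(i > n, 2 * n + 1 - i, i))
  oracle <- vapply(1:60, function(i) {
    m <- mean(ramp_line[refl((i - 10):(i + 10), 60)])
    max(0, ramp_line[i] - m)
  }, 0)
  expect_equal(unclass(res)[, 30, 1], oracle, tolerance = 1e-12)
  expect_true(all(abs(unclass(res)[11:50, 30, 1]) < 1e-9))

  expect_warning(subtract_boxcar(const, radius_um = 1), "one pixel")
  expect_error(subtract_boxcar(as_volume(array(1, c(4, 4, 1)),
                                         state = "raw")), "8-bit")
})

test_that("gaussian_smooth conserves mass and has the right footprint", {
  # interior-supported impulse: kernel normalization conserves the sum
  v <- array(0, c(41, 41, 11)); v[21, 21, 6] <- 1000
  sm <- gaussian_smooth(as_volume(v), sigma_um = 80)
  expect_equal(sum(sm), 1000, tolerance = 1e-3)

  # per-axis sd of the impulse response matches sigma in voxel units
  d <- dim(sm)
  ix <- seq_len(d[1]); iz <- seq_len(d[3])
  wx <- apply(unclass(sm), 1, sum)
  sd_x <- sqrt(sum(wx * (ix - 21)^2) / sum(wx))
  expect_equal(sd_x, 80 / 16, tolerance = 0.02)
  wz <- apply(unclass(sm), 3, sum)
  sd_z <- sqrt(sum(wz * (iz - 6)^2) / sum(wz))
  expect_equal(sd_z, 80 / 125, tolerance = 0.05)

  # sigma -> 0 returns the input unchanged
  expect_equal(unclass(gaussian_smooth(as_volume(v), 0)), v,
               ignore_attr = TRUE)
})

test_that("count_objects applies threshold, size filter and connectivity", {
  v <- array(0, c(20, 20, 12))
  v[2:5, 2:5, 2:5] <- 255       # 64 voxels, passes min 50
  v[12:15, 12:15, 7:10] <- 255  # 64 voxels
  det <- count_objects(as_volume(v))
  expect_equal(det$count, 2)
  expect_equal(det$objects$voxels, c(64, 64))

  # 27 voxels fails the published size filter of 50
  v2 <- array(0, c(20, 20, 12)); v2[2:4, 2:4, 2:4] <- 255
  expect_equal(count_objects(as_volume(v2))$count, 0)

  # all-zero volume: empty result is valid
  expect_equal(count_objects(as_volume(array(0, c(8, 8, 4))))$count, 0)

  # corner-touching voxels: one object at 26-connectivity, two at 6
  v3 <- array(0, c(6, 6, 6)); v3[2, 2, 2] <- 255; v3[3, 3, 3] <- 255
  p26 <- detection_params(min_voxels = 1, connectivity = 26)
  p6 <- detection_params(min_voxels = 1, connectivity = 6)
  expect_equal(count_objects(as_volume(v3), p26)$count, 1)
  expect_equal(count_objects(as_volume(v3), p6)$count, 2)
})

test_that("centroids are reported in physical micrometres", {
  v <- array(0, c(16, 16, 8)); v[3:6, 5:8, 2:3] <- 255
  det <- count_objects(as_volume(v), detection_params(min_voxels = 1))
  expect_equal(det$objects$x_um, mean(c(3:6) - 1) * 16)
  expect_equal(det$objects$y_um, mean(c(5:8) - 1) * 16)
  expect_equal(det$objects$z_um, mean(c(2:3) - 1) * 125)
  expect_equal(det$objects$peak_activity, 255)
})

test_that("labeling agrees with a flood-fill oracle on random volumes", {
  set.seed(202)
  for (i in 1:6) {
    d <- sample(8:20, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.25, d)
    conn <- sample(c(6L, 18L, 26L), 1)
    ours <- bspim:::cpp_label3d(mask, d, conn)
    oracle <- label3d_naive(mask, conn)
    # identical partitions and identical scan-order numbering
    expect_identical(as.integer(ours), as.integer(oracle))
  }
})

test_that("detected count is monotone in threshold and size filter", {
  # three unimodal blobs of increasing peak height: raising the threshold
  # or the size filter can only remove objects, never create them
  blob_volume <- function() {
    d <- c(30, 30, 12)
    v <- array(0, d)
    centers <- rbind(c(7, 7, 4), c(20, 10, 7), c(12, 23, 9))
    peaks <- c(100, 180, 250)
    for (b in 1:3) {
      for (k in 1:d[3]) {
        dx <- outer((1:d[1] - centers[b, 1])^2,
                    (1:d[2] - centers[b, 2])^2, "+")
        v[, , k] <- v[, , k] +
          peaks[b] * exp(-(dx + 4 * (k - centers[b, 3])^2) / (2 * 2.5^2))
      }
    }
    as_volume(v)
  }
  v <- blob_volume()
  counts_thr <- vapply(c(20, 60, 120, 200, 254), function(th) {
    count_objects(v, detection_params(threshold = th, min_voxels = 2))$count
  }, 0L)
  expect_equal(counts_thr[1], 3)
  expect_true(all(diff(counts_thr) <= 0))
  expect_equal(counts_thr[5], 0)
  counts_mv <- vapply(c(1, 10, 50, 200, 5000), function(mv) {
    count_objects(v, detection_params(threshold = 60, min_voxels = mv))$count
  }, 0L)
  expect_true(all(diff(counts_mv) <= 0))
  expect_equal(counts_mv[5], 0)
})

test_that("one nematode under overlapping 1 mm sheets yields one object", {
  sc <- make_scene(1, grid_shape = c(128, 128, 24), seed = 44)
  acq <- acquisition_config(n_positions = 24)
  det <- detect_from_volume(simulate_gd_volume(sc, acq, seed = 44))
  expect_equal(det$count, 1)
  # despite the footprint spanning ~8 positions
  expect_gte(length(worm_z_footprint <- bspim:::worm_position_footprint(
    sc, acq, 1)), 7)
  expect_lt(abs(det$objects$z_um - sc$nematodes$z_um), 300)
})

test_that("the full pipeline separates live from dead nematodes", {
  sc_live <- make_scene(5, grid_shape = c(256, 256, 40), seed = 91)
  acq <- acquisition_config(n_positions = 40)
  scan <- simulate_scan(sc_live, acq, seed = 91)
  det <- detect_nematodes(scan)
  expect_equal(det$count, 5)
  expect_false(is.null(attr(det, "stages")))

  sc_dead <- make_scene(5, grid_shape = c(256, 256, 40), alive_fraction = 0,
                        seed = 91)
  det0 <- detect_from_volume(simulate_gd_volume(sc_dead, acq, seed = 91))
  expect_equal(det0$count, 0)

  # empty scene
  sc_none <- make_scene(0, grid_shape = c(128, 128, 12), seed = 92)
  det_none <- detect_from_volume(simulate_gd_volume(
    sc_none, acquisition_config(n_positions = 12), seed = 92))
  expect_equal(det_none$count, 0)
})

test_that("crop_volume selects a physical region of interest", {
  v <- as_volume(array(seq_len(8 * 8 * 10), c(8, 8, 10)), state = "raw")
  cv <- crop_volume(v, list(z_um = c(0, 500)))
  expect_equal(dim(cv), c(8, 8, 4))
  expect_error(crop_volume(v, list(x_um = c(1e5, 2e5))), "no voxels")
})
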