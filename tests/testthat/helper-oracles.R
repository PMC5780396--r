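# Independent brute-force oracles and small fixture builders.

# GD by direct double loop over (i, j): sum_i sum_{j>=1, i+j<=N} |I_{i+j}-I_i|
gd_naive <- function(series, max_lag = Inf) {
  n <- length(series)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n - i)) {
      if (j <= max_lag) acc <- acc + abs(series[i + j] - series[i])
    }
  }
  acc
}

gd_naive_stack <- function(stack, max_lag = Inf) {
  d <- dim(stack)
  out <- matrix(0, d[1], d[2])
  for (a in seq_len(d[1])) {
    for (b in seq_len(d[2])) {
      out[a, b] <- gd_naive(stack[a, b, ], max_lag)
    }
  }
  out
}

# 3D connected components by breadth-first flood fill
label3d_naive <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (p in which(mask)) {
    if (lab[p]) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (q - 1) %% d[1] + 1
      j <- ((q - 1) %/% d[1]) %% d[2] + 1
      k <- (q - 1) %/% (d[1] * d[2]) + 1
      for (o in seq_len(nrow(offs))) {
        i2 <- i + offs[o, 1]; j2 <- j + offs[o, 2]; k2 <- k + offs[o, 3]
        if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] ||
            k2 < 1 || k2 > d[3]) next
        q2 <- (k2 - 1) * d[1] * d[2] + (j2 - 1) * d[1] + i2
        if (mask[q2] && !lab[q2]) {
          lab[q2] <- nxt
          queue <- c(queue, q2)
        }
      }
    }
  }
  lab
}

# small acquisition used throughout the unit tests
tiny_acq <- function(...) {
  acquisition_config(frames_per_position = 16, n_positions = 12, ...)
}

tiny_scene <- function(n = 1, nx = 96, nz = 12, ...) {
  # short bodies by default so small grids can host them
  args <- utils::modifyList(list(grid_shape = c(nx, nx, nz),
                                 length_range_um = c(150, 350)),
                            list(...))
  do.call(make_scene, c(list(n), args))
}

# wrap a plain array as a gd_volume for filter/count unit tests
as_volume <- function(arr, voxel = c(16, 16, 125), state = "8bit") {
  bspim:::new_gd_volume(arr, voxel_size_um = voxel, state = state)
}
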