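#' Build a synthetic ground-truth scene of nematodes in transparent soil
#'
#' Creates the ground truth for a simulated BSPIM acquisition: a calibrated
#' voxel grid containing capsule-shaped nematodes (a cylinder with
#' hemispherical caps), optionally a root (rendered as a sensor-saturating
#' region, mimicking the high-exposure trick used to blot out root
#' biospeckle) and a static speckle background. Live nematodes are assigned a
#' temporal decorrelation coefficient `rho_live` < 1; heat-killed nematodes
#' keep the background coefficient `rho_bg`, which makes them statistically
#' indistinguishable from the static matrix in time while remaining slightly
#' brighter (refractive) in brightfield.
#'
#' Placement is rejection-sampled so that in-plane distances between nematode
#' body segments are at least `min_separation_um`, keeping the ground-truth
#' count well defined after the detection pipeline's 80 um smoothing.
#'
#' @param n_nematodes Number of nematodes to place (>= 0).
#' @param alive_fraction Fraction of nematodes that are alive; the live count
#'   is `round(alive_fraction * n_nematodes)`.
#' @param grid_shape Integer vector `(nx, ny, nz)`: image size in pixels and
#'   number of z planes (one per stage position at default settings).
#' @param voxel_size_xy_um In-plane pixel size, micrometres.
#' @param z_step_um Plane spacing in z, micrometres.
#' @param include_root Add a horizontal root crossing the field of view,
#'   rendered saturated.
#' @param clutter_sd Log-scale standard deviation of the static background
#'   brightness texture (0 = optically clean medium; ~0.8 emulates the
#'   refractive-index heterogeneity of soil + colloid samples).
#' @param clutter_scale_px Correlation length (pixels) of the clutter texture.
#' @param rho_live Frame-to-frame field decorrelation coefficient at live
#'   nematodes, in `[0, 1]` (lower = more activity).
#' @param rho_bg Background decorrelation coefficient, near 1 (1 = perfectly
#'   static matrix).
#' @param length_range_um Range the nematode body lengths are drawn from;
#'   must lie within the 40-1500 um envelope of free-living nematodes.
#' @param width_um Body width, at most ~30 um.
#' @param brightness Static brightness factor of nematode tissue relative to
#'   the background speckle mean (slightly refractive, > 1).
#' @param wriggle_um Amplitude of body motion during one frame stack,
#'   micrometres. A live animal wriggles while the 64 frames are recorded,
#'   so the region of decorrelating speckle is the body capsule dilated by
#'   this amount; it does not affect dead animals or the brightfield body
#'   footprint.
#' @param max_tilt_deg Maximum out-of-plane tilt of the body axis, degrees.
#' @param min_separation_um Minimum in-plane distance between body segments.
#' @param margin_um Clearance kept between any nematode and the grid faces.
#' @param seed Integer seed; placement is reproducible from it.
#'
#' @return An object of class `bspim_scene`: a list with a `nematodes` tibble
#'   (id, centroid in um, orientation, length, width, alive, rho,
#'   brightness), optional `root`, grid calibration and background
#'   parameters.
#' @examples
#' make_scene(3, seed = 1, grid_shape = c(96, 96, 16))
#' @export
make_scene <- function(n_nematodes,
                       alive_fraction = 1,
                       grid_shape = c(256, 256, 80),
                       voxel_size_xy_um = 16,
                       z_step_um = 125,
                       include_root = FALSE,
                       clutter_sd = 0,
                       clutter_scale_px = 3,
                       rho_live = 0.7,
                       rho_bg = 1,
                       length_range_um = c(200, 800),
                       width_um = 25,
                       brightness = 1.5,
                       wriggle_um = 45,
                       max_tilt_deg = 30,
                       min_separation_um = 400,
                       margin_um = 200,
                       seed = 1) {
  stopifnot(n_nematodes >= 0, length(grid_shape) == 3)
  if (rho_live < 0 || rho_live > 1 || rho_bg < 0 || rho_bg > 1) {
    stop("decorrelation coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (alive_fraction < 0 || alive_fraction > 1) {
    stop("`alive_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length_range_um[1] < 40 || length_range_um[2] > 1500) {
    stop("nematode lengths must lie within the 40-1500 um envelope",
         call. = FALSE)
  }
  if (width_um > 30) {
    stop("nematode width must not exceed ~30 um", call. = FALSE)
  }
  nx <- as.integer(grid_shape[1]); ny <- as.integer(grid_shape[2])
  nz <- as.integer(grid_shape[3])
  ext <- c(nx * voxel_size_xy_um, ny * voxel_size_xy_um, nz * z_step_um)
  r <- width_um / 2

  # feasibility: the smallest admissible body must fit the grid
  if (n_nematodes > 0) {
    h_min <- length_range_um[1] / 2
    if (2 * (h_min * cos(pi / 4) + r + margin_um) >= min(ext[1], ext[2]) ||
        2 * (r + margin_um) >= ext[3]) {
      stop(sprintf(paste0(
        "grid of %g x %g x %g um is too small to contain a %g um ",
        "nematode with a %g um margin"),
        ext[1], ext[2], ext[3], length_range_um[1], margin_um),
        call. = FALSE)
    }
  }

  worms <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    n_alive <- round(alive_fraction * n_nematodes)
    alive <- rep(FALSE, n_nematodes)
    if (n_alive > 0) alive[sample.int(n_nematodes)[seq_len(n_alive)]] <- TRUE
    placed <- vector("list", n_nematodes)
    segs <- matrix(numeric(0), ncol = 4)  # accepted xy segments
    i <- 0L
    tries <- 0L
    max_tries <- max(4000L, 2000L * n_nematodes)
    while (i < n_nematodes) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0(
          "could not place nematode %d of %d: minimum in-plane separation ",
          "of %g um cannot be met in a %g x %g x %g um grid"),
          i + 1L, n_nematodes, min_separation_um, ext[1], ext[2], ext[3]),
          call. = FALSE)
      }
      len <- runif(1, length_range_um[1], length_range_um[2])
      h <- len / 2
      phi <- runif(1, 0, 2 * pi)
      theta <- runif(1, -1, 1) * max_tilt_deg * pi / 180
      u <- c(cos(theta) * cos(phi), cos(theta) * sin(phi), sin(theta))
      mx <- abs(u[1]) * h + r + margin_um
      my <- abs(u[2]) * h + r + margin_um
      mz <- abs(u[3]) * h + r + margin_um
      # a candidate too long/tilted for the grid is resampled
      if (2 * mx >= ext[1] || 2 * my >= ext[2] || 2 * mz >= ext[3]) next
      ctr <- c(runif(1, mx, ext[1] - mx),
               runif(1, my, ext[2] - my),
               runif(1, mz, ext[3] - mz))
      a <- ctr[1:2] - h * u[1:2]
      b <- ctr[1:2] + h * u[1:2]
      ok <- TRUE
      if (nrow(segs) > 0) {
        for (s in seq_len(nrow(segs))) {
          d <- seg2_dist(a, b, segs[s, 1:2], segs[s, 3:4])
          if (d < min_separation_um) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      i <- i + 1L
      segs <- rbind(segs, c(a, b))
      placed[[i]] <- list(ctr = ctr, u = u, len = len)
    }
    if (n_nematodes == 0) {
      tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                     z_um = numeric(), ux = numeric(), uy = numeric(),
                     uz = numeric(), length_um = numeric(),
                     width_um = numeric(), alive = logical(),
                     rho = numeric(), brightness = numeric(),
                     wriggle_um = numeric())
    } else {
      tibble::tibble(
        id = seq_len(n_nematodes),
        x_um = vapply(placed, function(p) p$ctr[1], 0),
        y_um = vapply(placed, function(p) p$ctr[2], 0),
        z_um = vapply(placed, function(p) p$ctr[3], 0),
        ux = vapply(placed, function(p) p$u[1], 0),
        uy = vapply(placed, function(p) p$u[2], 0),
        uz = vapply(placed, function(p) p$u[3], 0),
        length_um = vapply(placed, function(p) p$len, 0),
        width_um = width_um,
        alive = alive,
        rho = ifelse(alive, rho_live, rho_bg),
        brightness = brightness,
        wriggle_um = ifelse(alive, wriggle_um, 0)
      )
    }
  })

  root <- NULL
  if (isTRUE(include_root)) {
    root <- list(start_um = c(0, ext[2] / 2, ext[3] / 2),
                 end_um = c(ext[1], ext[2] / 2, ext[3] / 2),
                 radius_um = 150)
  }

  structure(
    list(nematodes = worms, root = root,
         grid_shape = c(nx, ny, nz),
         voxel_size_xy_um = voxel_size_xy_um, z_step_um = z_step_um,
         rho_bg = rho_bg, clutter_sd = clutter_sd,
         clutter_scale_px = clutter_scale_px, seed = as.integer(seed)),
    class = "bspim_scene"
  )
}

#' @export
print.bspim_scene <- function(x, ...) {
  cat("<bspim scene>\n")
  cat(sprintf("  grid %d x %d x %d (%g um/px, %g um z step)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size_xy_um, x$z_step_um))
  cat(sprintf("  %d nematodes (%d alive), clutter sd %g, root: %s\n",
              nrow(x$nematodes), sum(x$nematodes$alive), x$clutter_sd,
              if (is.null(x$root)) "no" else "yes"))
  invisible(x)
}

# Distance between two 2D segments a1-a2, b1-b2.
seg2_dist <- function(a1, a2, b1, b2) {
  if (segs_intersect(a1, a2, b1, b2)) return(0)
  min(pt_seg_dist(a1, b1, b2), pt_seg_dist(a2, b1, b2),
      pt_seg_dist(b1, a1, a2), pt_seg_dist(b2, a1, a2))
}

pt_seg_dist <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else max(0, min(1, sum((p - a) * ab) / denom))
  sqrt(sum((a + t * ab - p)^2))
}

segs_intersect <- function(a1, a2, b1, b2) {
  ccw <- function(p, q, r) {
    (r[2] - p[2]) * (q[1] - p[1]) - (q[2] - p[2]) * (r[1] - p[1])
  }
  d1 <- ccw(b1, b2, a1); d2 <- ccw(b1, b2, a2)
  d3 <- ccw(a1, a2, b1); d4 <- ccw(a1, a2, b2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# --- slab geometry -----------------------------------------------------------

# Maps describing what one light-sheet position sees: per-pixel decorrelation
# (live bodies dilated by their wriggle amplitude), static brightness,
# saturation mask and object mask.
slab_maps <- function(scene, z_center_um, thickness_um) {
  nx <- scene$grid_shape[1]; ny <- scene$grid_shape[2]
  px <- scene$voxel_size_xy_um
  rho <- matrix(scene$rho_bg, nx, ny)
  bright <- matrix(1, nx, ny)
  sat <- matrix(FALSE, nx, ny)
  obj <- matrix(FALSE, nx, ny)
  zlo <- z_center_um - thickness_um / 2
  zhi <- z_center_um + thickness_um / 2

  rasterize <- function(a_xy, b_xy, radius) {
    # pixels whose centers lie within `radius` of the xy segment a-b;
    # a sub-pixel radius is widened so thin bodies still cover one pixel row
    r_eff <- max(radius, 0.75 * px)
    i0 <- max(1L, floor((min(a_xy[1], b_xy[1]) - r_eff) / px - 1) + 1L)
    i1 <- min(nx, ceiling((max(a_xy[1], b_xy[1]) + r_eff) / px + 1))
    j0 <- max(1L, floor((min(a_xy[2], b_xy[2]) - r_eff) / px - 1) + 1L)
    j1 <- min(ny, ceiling((max(a_xy[2], b_xy[2]) + r_eff) / px + 1))
    if (i0 > i1 || j0 > j1) return(NULL)
    ii <- i0:i1; jj <- j0:j1
    xs <- (ii - 0.5) * px; ys <- (jj - 0.5) * px
    ab <- b_xy - a_xy
    denom <- sum(ab^2)
    gx <- matrix(xs, length(ii), length(jj))
    gy <- matrix(ys, length(ii), length(jj), byrow = TRUE)
    tt <- if (denom == 0) {
      matrix(0, length(ii), length(jj))
    } else {
      pmin(1, pmax(0, ((gx - a_xy[1]) * ab[1] + (gy - a_xy[2]) * ab[2]) /
                     denom))
    }
    dx <- a_xy[1] + tt * ab[1] - gx
    dy <- a_xy[2] + tt * ab[2] - gy
    m <- (dx * dx + dy * dy) <= r_eff^2
    if (!any(m)) return(NULL)
    list(rows = ii, cols = jj, mask = m)
  }

  clip_capsule <- function(ctr, u, half, radius) {
    # parameter range of the axis segment whose capsule intersects the slab
    if (abs(u[3]) < 1e-12) {
      if (ctr[3] + radius < zlo || ctr[3] - radius > zhi) return(NULL)
      s <- c(-1, 1)
    } else {
      s1 <- (zlo - radius - ctr[3]) / (u[3] * half)
      s2 <- (zhi + radius - ctr[3]) / (u[3] * half)
      s <- sort(c(s1, s2))
      s <- c(max(-1, s[1]), min(1, s[2]))
      if (s[1] > s[2]) return(NULL)
    }
    a <- ctr[1:2] + s[1] * half * u[1:2]
    b <- ctr[1:2] + s[2] * half * u[1:2]
    list(a = a, b = b)
  }

  w <- scene$nematodes
  if (nrow(w) > 0) {
    if (is.null(w$wriggle_um)) w$wriggle_um <- 0
    for (k in seq_len(nrow(w))) {
      body_r <- w$width_um[k] / 2
      active_r <- body_r + w$wriggle_um[k]
      # decorrelating region: body swept by wriggling during the stack
      if (w$rho[k] < 1) {
        seg <- clip_capsule(c(w$x_um[k], w$y_um[k], w$z_um[k]),
                            c(w$ux[k], w$uy[k], w$uz[k]),
                            w$length_um[k] / 2, active_r)
        if (!is.null(seg)) {
          ras <- rasterize(seg$a, seg$b, active_r)
          if (!is.null(ras)) {
            sub_rho <- rho[ras$rows, ras$cols, drop = FALSE]
            sub_rho[ras$mask] <- pmin(sub_rho[ras$mask], w$rho[k])
            rho[ras$rows, ras$cols] <- sub_rho
          }
        }
      }
      # the body itself: brighter (refractive) in brightfield
      seg <- clip_capsule(c(w$x_um[k], w$y_um[k], w$z_um[k]),
                          c(w$ux[k], w$uy[k], w$uz[k]),
                          w$length_um[k] / 2, body_r)
      if (is.null(seg)) next
      ras <- rasterize(seg$a, seg$b, body_r)
      if (is.null(ras)) next
      sub_b <- bright[ras$rows, ras$cols, drop = FALSE]
      sub_b[ras$mask] <- w$brightness[k]
      bright[ras$rows, ras$cols] <- sub_b
      sub_o <- obj[ras$rows, ras$cols, drop = FALSE]
      sub_o[ras$mask] <- TRUE
      obj[ras$rows, ras$cols] <- sub_o
    }
  }
  if (!is.null(scene$root)) {
    rt <- scene$root
    seg <- clip_capsule((rt$start_um + rt$end_um) / 2,
                        (rt$end_um - rt$start_um) /
                          sqrt(sum((rt$end_um - rt$start_um)^2)),
                        sqrt(sum((rt$end_um - rt$start_um)^2)) / 2,
                        rt$radius_um)
    if (!is.null(seg)) {
      ras <- rasterize(seg$a, seg$b, rt$radius_um)
      if (!is.null(ras)) {
        sub <- sat[ras$rows, ras$cols, drop = FALSE]
        sub[ras$mask] <- TRUE
        sat[ras$rows, ras$cols] <- sub
        sub_o <- obj[ras$rows, ras$cols, drop = FALSE]
        sub_o[ras$mask] <- TRUE
        obj[ras$rows, ras$cols] <- sub_o
      }
    }
  }
  list(rho = rho, brightness = bright, saturate = sat, obj = obj)
}

# z coordinate (um) of stage position index i (1-based)
position_z_um <- function(scene, index) (index - 0.5) * scene$z_step_um

# Ground-truth stage positions whose slab sees a given nematode
worm_position_footprint <- function(scene, acq, k) {
  w <- scene$nematodes[k, ]
  hz <- abs(w$uz) * w$length_um / 2 + w$width_um / 2 +
    if (is.null(w$wriggle_um)) 0 else w$wriggle_um
  zlo <- w$z_um - hz - acq$sheet_thickness_um / 2
  zhi <- w$z_um + hz + acq$sheet_thickness_um / 2
  idx <- seq_len(acq$n_positions)
  zc <- (idx - 0.5) * scene$z_step_um
  idx[zc > zlo & zc < zhi]
}
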