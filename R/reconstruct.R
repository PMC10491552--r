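#' Pixel-nearest-neighbour reconstruction settings
#'
#' @param voxel_spacing Isotropic voxel size (mm) of the output grid.
#' @param fill_distance Hole-filling search radius in voxels (Chebyshev);
#'   empty voxels further than this from any filled voxel stay 0.
#' @return An object of class `us_pnn_config`.
#' @export
pnn_config <- function(voxel_spacing = 0.22, fill_distance = 3) {
  if (fill_distance < 0 || fill_distance != round(fill_distance)) {
    stop_us("fill_distance must be a non-negative integer", "us_invalid_config")
  }
  stopifnot(voxel_spacing > 0)
  structure(list(voxel_spacing = voxel_spacing,
                 fill_distance = as.integer(fill_distance),
                 compounding = "maximum"),
            class = "us_pnn_config")
}

# surface row of one column, linearly interpolated at the threshold crossing
surface_cross <- function(col, threshold, subpixel = TRUE) {
  r <- which(col >= threshold)[1]
  if (is.na(r)) return(NA_real_)
  if (!subpixel || r == 1) return(as.numeric(r))
  g0 <- col[r - 1]; g1 <- col[r]
  if (g1 == g0) return(as.numeric(r))
  (r - 1) + (threshold - g0) / (g1 - g0)
}

#' Estimate the temporal offset between tracking and image streams
#'
#' Recovers the lag between the tracking clock and the image clock by
#' normalized cross-correlation of an image-derived motion signal (the
#' sub-pixel surface row of the mid-lateral image column per frame) with the
#' probe-movement signals from tracking. The surface row responds both to
#' elevation progress (through the surface curvature) and to axial probe
#' motion (tremor), so the detrended axial and elevation tracking channels
#' are both scanned and the channel with the strongest correlation peak
#' wins; the raw elevation signal is the fallback when neither fluctuates.
#' Both signals are resampled to a common grid of a quarter frame interval,
#' so the lag resolution is well below half the frame interval. The
#' returned offset is the value to pass to [apply_temporal_offset()]:
#' tracking clock minus image clock, in ms.
#'
#' @param tracking Tracking tibble (`t, x, y, z, ...`).
#' @param frames A [frame_stream()].
#' @param max_lag_s Largest lag magnitude scanned (s).
#' @param threshold Gray threshold for the surface row signal.
#' @param min_correlation Estimates whose best absolute correlation falls
#'   below this are rejected as unreliable.
#' @return A list of class `us_temporal_offset` with elements `offset_ms`,
#'   `correlation`, `channel` and the scanned `lags` tibble.
#' @export
temporal_offset <- function(tracking, frames, max_lag_s = 0.5,
                            threshold = 100, min_correlation = 0.5) {
  stopifnot(inherits(frames, "us_frames"))
  if (diff(range(frames$t)) < 2 || diff(range(tracking$t)) < 2) {
    stop_us("streams must span at least 2 s of motion", "us_short_stream")
  }
  mid <- ceiling(ncol(frames$frames[[1]]) / 2)
  srow <- vapply(frames$frames,
                 function(f) surface_cross(f[, mid], threshold), numeric(1))
  if (anyNA(srow)) {
    stop_us("surface not detected in every frame; cannot form image motion signal",
            "us_no_surface")
  }
  dt <- stats::median(diff(frames$t)) / 4
  grid <- seq(max(min(frames$t), min(tracking$t)),
              min(max(frames$t), max(tracking$t)), by = dt)
  s_img <- stats::approx(frames$t, srow, xout = grid, rule = 2)$y
  if (sd(s_img) < 1e-9) {
    stop_us("motionless streams: lag is undefined", "us_undefined_lag")
  }
  # first differences remove the smooth sweep trend exactly, leaving the
  # velocity-variation structure that identifies the lag; a light moving
  # average suppresses resampled tracking noise
  smooth3 <- function(v) stats::filter(v, rep(1 / 15, 15), sides = 2) |>
    as.numeric() |>
    (\(x) { x[is.na(x)] <- v[is.na(x)]; x })()
  trk_sig <- function(col, do_diff) {
    v <- stats::approx(tracking$t, tracking[[col]], xout = grid, rule = 2)$y
    if (do_diff) diff(smooth3(v)) else v
  }
  candidates <- list(
    axial_detrended = trk_sig("y", TRUE),
    elevation_detrended = trk_sig("z", TRUE),
    elevation = trk_sig("z", FALSE)
  )
  K <- min(length(grid) - 4, ceiling(max_lag_s / dt))
  lags <- (-K):K
  s_img_det <- diff(smooth3(s_img))
  scan <- function(s_trk, img) {
    n <- length(img)
    if (sd(s_trk) < 1e-9 || sd(img) < 1e-9) return(NULL)
    a0 <- (img - mean(img)) / sd(img)
    b0 <- (s_trk - mean(s_trk)) / sd(s_trk)
    vapply(lags, function(k) {
      if (k >= 0) {
        stats::cor(a0[seq_len(n - k)], b0[seq_len(n - k) + k])
      } else {
        stats::cor(a0[seq_len(n + k) - k], b0[seq_len(n + k)])
      }
    }, numeric(1))
  }
  pick <- function(nms) {
    best <- NULL
    for (nm in nms) {
      img <- if (grepl("detrended", nm)) s_img_det else s_img
      cors <- scan(candidates[[nm]], img)
      if (is.null(cors)) next
      i <- which.max(abs(cors))
      if (is.null(best) || abs(cors[i]) > abs(best$correlation)) {
        best <- list(channel = nm, correlation = cors[i], lag = lags[i],
                     cors = cors)
      }
    }
    best
  }
  # detrended channels carry the velocity-variation structure that makes the
  # lag identifiable; the raw elevation ramp is only a last resort
  best <- pick(c("axial_detrended", "elevation_detrended"))
  if (is.null(best) || abs(best$correlation) < min_correlation) {
    best <- pick("elevation") %||% best
  }
  if (is.null(best)) {
    stop_us("motionless streams: lag is undefined", "us_undefined_lag")
  }
  if (abs(best$correlation) < min_correlation) {
    stop_us(sprintf("temporal calibration unreliable: best |correlation| %.2f < %.2f",
                    abs(best$correlation), min_correlation),
            "us_undefined_lag")
  }
  # parabolic refinement of the correlation peak for sub-sample lag
  i <- which(lags == best$lag)
  lag_ref <- best$lag
  if (i > 1 && i < length(lags)) {
    c3 <- abs(best$cors[(i - 1):(i + 1)])
    den <- c3[1] - 2 * c3[2] + c3[3]
    if (is.finite(den) && den < 0) {
      lag_ref <- best$lag + 0.5 * (c3[1] - c3[3]) / den
    }
  }
  # a sample recorded at tracking stamp t corresponds to true time
  # t - offset, so correlation peaks where the scan shift equals the offset
  structure(list(offset_ms = lag_ref * dt * 1000,
                 correlation = best$correlation, channel = best$channel,
                 lags = tibble::tibble(lag_ms = lags * dt * 1000,
                                       correlation = best$cors)),
            class = "us_temporal_offset")
}

#' @export
print.us_temporal_offset <- function(x, ...) {
  cat(sprintf("<us_temporal_offset> %.1f ms (|r| = %.3f)\n",
              x$offset_ms, abs(x$correlation)))
  invisible(x)
}

#' Shift tracking timestamps onto the image clock
#'
#' @param tracking Tracking tibble.
#' @param offset_ms Tracking clock minus image clock (ms), e.g. the
#'   calibration value -30 or an estimate from [temporal_offset()].
#' @return The tracking tibble with corrected timestamps.
#' @export
apply_temporal_offset <- function(tracking, offset_ms) {
  tracking$t <- tracking$t - offset_ms / 1000
  tracking
}

#' Pixel-nearest-neighbour volume reconstruction
#'
#' Reconstructs a tracked freehand sweep on an isotropic voxel grid. Bin
#' step: every frame pixel is mapped through its (linearly interpolated) pose
#' to the nearest voxel and deposited with maximum-value compounding, so a
#' voxel hit by several frames keeps the brightest pixel. Fill step: empty
#' voxels within `fill_distance` (Chebyshev radius, voxels) of a filled
#' voxel receive the value of the nearest filled voxel (Euclidean distance;
#' ties broken by the smallest voxel linear index); voxels beyond the radius
#' remain 0. Frames without bracketing tracking samples are dropped with a
#' message.
#'
#' Tracking timestamps must already be on the image clock
#' (see [apply_temporal_offset()]).
#'
#' @param frames A [frame_stream()].
#' @param tracking Tracking tibble on the image clock.
#' @param pnn A [pnn_config()].
#' @return An `us_volume` with isotropic spacing and method `"pnn"`.
#' @export
pnn_reconstruct <- function(frames, tracking, pnn = pnn_config()) {
  stopifnot(inherits(frames, "us_frames"))
  validate_trajectory(tracking)
  v <- pnn$voxel_spacing
  geom <- frames$geom
  keep <- frames$t >= min(tracking$t) & frames$t <= max(tracking$t)
  if (!all(keep)) {
    message(sprintf("pnn_reconstruct: dropped %d frame(s) without bracketing tracking samples",
                    sum(!keep)))
  }
  if (sum(keep) < 2) {
    stop_us("fewer than 2 frames have bracketing tracking samples", "us_no_overlap")
  }
  fidx <- which(keep)
  interp <- function(col) stats::approx(tracking$t, tracking[[col]],
                                        xout = frames$t[fidx])$y
  poses <- tibble::tibble(t = frames$t[fidx], x = interp("x"), y = interp("y"),
                          z = interp("z"), rx = interp("rx"),
                          ry = interp("ry"), rz = interp("rz"))

  nr <- nrow(frames$frames[[1]]); nc <- ncol(frames$frames[[1]])
  yi <- (seq_len(nr) - 1) * geom$pixel_spacing_axial
  xj <- (seq_len(nc) - 1) * geom$pixel_spacing_lateral

  # world-coordinate bounds from the frame-plane corners (exact: linear map)
  corners <- cbind(x = c(0, max(xj), 0, max(xj)), y = c(0, 0, max(yi), max(yi)))
  lo <- c(Inf, Inf, Inf); hi <- -lo
  world_corner <- function(pose) {
    R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
    p <- c(pose$x, pose$y, pose$z)
    w <- t(R[, 1:2] %*% t(corners)) + matrix(p, 4, 3, byrow = TRUE)
    w  # columns: lateral, axial, elevation
  }
  for (k in seq_len(nrow(poses))) {
    w <- world_corner(poses[k, ])
    # reorder to (axial, lateral, elevation)
    wa <- cbind(w[, 2], w[, 1], w[, 3])
    lo <- pmin(lo, apply(wa, 2, min)); hi <- pmax(hi, apply(wa, 2, max))
  }
  origin <- round(lo / v) * v
  dims <- pmax(as.integer(floor((hi - origin) / v + 0.5)) + 1L, 1L)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]

  vol <- numeric(n1 * n2 * n3)
  filled <- logical(n1 * n2 * n3)
  for (k in seq_len(nrow(poses))) {
    pose <- poses[k, ]
    R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
    p <- c(pose$x, pose$y, pose$z)
    wx <- outer(R[1, 2] * yi, R[1, 1] * xj, "+") + p[1]
    wy <- outer(R[2, 2] * yi, R[2, 1] * xj, "+") + p[2]
    wz <- outer(R[3, 2] * yi, R[3, 1] * xj, "+") + p[3]
    i <- as.integer(round((wy - origin[1]) / v)) + 1L
    j <- as.integer(round((wx - origin[2]) / v)) + 1L
    kk <- as.integer(round((wz - origin[3]) / v)) + 1L
    ok <- i >= 1L & i <= n1 & j >= 1L & j <= n2 & kk >= 1L & kk <= n3
    lin <- i[ok] + (j[ok] - 1L) * n1 + (kk[ok] - 1L) * (n1 * n2)
    val <- as.numeric(frames$frames[[fidx[k]]])[ok]
    # per-frame grouped maximum, then maximum compounding into the volume
    o <- order(lin, -val)
    first <- !duplicated(lin[o])
    lin2 <- lin[o][first]; val2 <- val[o][first]
    vol[lin2] <- pmax(vol[lin2], val2)
    filled[lin2] <- TRUE
  }

  if (pnn$fill_distance > 0 && any(!filled) && any(filled)) {
    vol <- pnn_fill(vol, filled, dims, pnn$fill_distance)
  }
  us_volume(array(vol, dim = dims), spacing = rep(v, 3), origin = origin,
            method = "pnn")
}

# nearest-filled-voxel hole filling within a Chebyshev radius.
# Offsets are visited in order of (Euclidean distance, linear displacement),
# so the first hit per empty voxel is the nearest filled voxel with ties
# broken by the smallest voxel linear index.
pnn_fill <- function(vol, filled, dims, d) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  off <- expand.grid(di = -d:d, dj = -d:d, dk = -d:d)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  dist2 <- off$di^2 + off$dj^2 + off$dk^2
  ldisp <- off$di + off$dj * n1 + off$dk * n1 * n2
  ord <- order(dist2, ldisp)
  off <- off[ord, ]; ldisp <- ldisp[ord]

  rem <- which(!filled)
  if (length(rem) == 0) return(vol)
  ai <- arrayInd(rem, dims)
  ri <- ai[, 1]; rj <- ai[, 2]; rk <- ai[, 3]
  for (m in seq_len(nrow(off))) {
    if (length(rem) == 0) break
    i2 <- ri + off$di[m]; j2 <- rj + off$dj[m]; k2 <- rk + off$dk[m]
    inb <- i2 >= 1L & i2 <= n1 & j2 >= 1L & j2 <= n2 & k2 >= 1L & k2 <= n3
    cand <- rem + ldisp[m]
    hit <- inb
    hit[inb] <- filled[cand[inb]]
    if (any(hit)) {
      vol[rem[hit]] <- vol[cand[hit]]
      keep <- !hit
      rem <- rem[keep]; ri <- ri[keep]; rj <- rj[keep]; rk <- rk[keep]
    }
  }
  vol
}
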