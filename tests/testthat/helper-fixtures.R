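# Small-geometry fixtures shared across tests. Tests choose compact image
# geometries so full pipelines run in seconds.

small_geom <- function(depth_cm = 4.3, spacing = 0.12, width_mm = 6,
                       fps = 10) {
  image_geometry(depth_cm = depth_cm, pixel_spacing_axial = spacing,
                 pixel_spacing_lateral = spacing, width_mm = width_mm,
                 fps = fps)
}

# phantom without speckle for deterministic geometry checks
quiet_phantom <- function(...) default_phantom(speckle_sigma = 0, ...)

# a volume with constant background and one bright point spread as a
# separable Gaussian (for profile metrics without running the renderer)
gaussian_point_volume <- function(dims = c(81, 21, 41),
                                  spacing = c(0.1, 0.1, 0.1),
                                  center = (dims + 1) / 2,
                                  sigma_mm = c(0.15, 0.15, 0.4),
                                  peak = 200, background = 20) {
  pr <- function(n, c0, s_mm, sp) exp(-(((seq_len(n) - c0) * sp)^2) / (2 * s_mm^2))
  a <- pr(dims[1], center[1], sigma_mm[1], spacing[1])
  b <- pr(dims[2], center[2], sigma_mm[2], spacing[2])
  c_ <- pr(dims[3], center[3], sigma_mm[3], spacing[3])
  arr <- background + peak * (a %o% b %o% c_)
  us_volume(arr, spacing = spacing)
}

# brute-force PNN oracle: exhaustive deposit-and-fill over all voxels,
# independent of the package implementation
brute_pnn <- function(points, values, dims, origin, v, fill_distance) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  vol <- array(0, dim = dims)
  filled <- array(FALSE, dim = dims)
  for (p in seq_len(nrow(points))) {
    i <- round((points[p, 1] - origin[1]) / v) + 1
    j <- round((points[p, 2] - origin[2]) / v) + 1
    k <- round((points[p, 3] - origin[3]) / v) + 1
    if (i < 1 || i > n1 || j < 1 || j > n2 || k < 1 || k > n3) next
    vol[i, j, k] <- max(vol[i, j, k], values[p])
    filled[i, j, k] <- TRUE
  }
  out <- vol
  for (i in seq_len(n1)) for (j in seq_len(n2)) for (k in seq_len(n3)) {
    if (filled[i, j, k]) next
    best <- NULL
    for (di in -fill_distance:fill_distance)
      for (dj in -fill_distance:fill_distance)
        for (dk in -fill_distance:fill_distance) {
          i2 <- i + di; j2 <- j + dj; k2 <- k + dk
          if (i2 < 1 || i2 > n1 || j2 < 1 || j2 > n2 || k2 < 1 || k2 > n3) next
          if (!filled[i2, j2, k2]) next
          d2 <- di^2 + dj^2 + dk^2
          lin <- i2 + (j2 - 1) * n1 + (k2 - 1) * n1 * n2
          if (is.null(best) || d2 < best$d2 ||
              (d2 == best$d2 && lin < best$lin)) {
            best <- list(d2 = d2, lin = lin, val = vol[i2, j2, k2])
          }
        }
    if (!is.null(best)) out[i, j, k] <- best$val
  }
  out
}
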