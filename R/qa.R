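# Image-quality metrics: contrast-resolution slope, -6 dB FWHM resolution,
# distance-calibration error and the surface-stability statistic.

#' Region of interest in voxel coordinates
#'
#' Box or cylinder ROI. Boxes are axis-aligned with half-extents in voxels;
#' cylinders have their axis along elevation, an in-plane radius in mm and an
#' elevation half-extent in voxels.
#'
#' @param center Integer voxel coordinate `(i, j, k)`.
#' @param half_extent Length-3 half extents in voxels (box).
#' @param shape `"box"` or `"cylinder"`.
#' @param radius_mm In-plane radius (cylinder).
#' @return An object of class `us_roi`.
#' @export
roi_spec <- function(center, half_extent = NULL, shape = c("box", "cylinder"),
                     radius_mm = NULL) {
  shape <- match.arg(shape)
  if (shape == "cylinder" && is.null(radius_mm)) {
    stop_us("cylinder ROI needs radius_mm", "us_invalid_roi")
  }
  structure(list(center = as.integer(center),
                 half_extent = if (!is.null(half_extent)) as.integer(half_extent),
                 shape = shape, radius_mm = radius_mm),
            class = "us_roi")
}

# linear voxel indices of an ROI; clip=TRUE truncates at the volume edge
# (used for marker searches), otherwise out-of-volume ROIs are an error
roi_indices <- function(volume, roi, clip = FALSE) {
  d <- dim(volume$data)
  c0 <- roi$center
  if (roi$shape == "box") {
    h <- roi$half_extent
    rng <- list(
      (c0[1] - h[1]):(c0[1] + h[1]),
      (c0[2] - h[2]):(c0[2] + h[2]),
      (c0[3] - h[3]):(c0[3] + h[3])
    )
    if (clip) {
      rng <- lapply(seq_len(3), function(a) rng[[a]][rng[[a]] >= 1 & rng[[a]] <= d[a]])
      if (any(lengths(rng) == 0)) {
        stop_us("ROI lies entirely outside the volume", "us_roi_outside")
      }
    } else if (any(vapply(seq_len(3),
                          function(a) any(rng[[a]] < 1 | rng[[a]] > d[a]),
                          logical(1)))) {
      stop_us("ROI extends outside the volume", "us_roi_outside")
    }
    g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  } else {
    h <- roi$half_extent
    rpx_i <- roi$radius_mm / volume$spacing[1]
    rpx_j <- roi$radius_mm / volume$spacing[2]
    ii <- (c0[1] - ceiling(rpx_i)):(c0[1] + ceiling(rpx_i))
    jj <- (c0[2] - ceiling(rpx_j)):(c0[2] + ceiling(rpx_j))
    kk <- (c0[3] - h[3]):(c0[3] + h[3])
    if (any(ii < 1 | ii > d[1]) || any(jj < 1 | jj > d[2]) ||
        any(kk < 1 | kk > d[3])) {
      stop_us("ROI extends outside the volume", "us_roi_outside")
    }
    g <- expand.grid(i = ii, j = jj, k = kk)
    el <- ((g$i - c0[1]) / rpx_i)^2 + ((g$j - c0[2]) / rpx_j)^2
    g <- g[el <= 1, ]
  }
  g$i + (g$j - 1) * d[1] + (g$k - 1) * d[1] * d[2]
}

#' Contrast-resolution slope
#'
#' Measures the mean gray value inside each of the five grayscale contrast
#' cylinders and fits an ordinary least-squares line of mean gray on the
#' nominal echo level. The slope of that line is the contrast resolution in
#' gray value per dB.
#'
#' @param volume An `us_volume`.
#' @param rois List of exactly 5 [roi_spec()] objects, one per cylinder, in
#'   the same order as `nominal_levels`.
#' @param nominal_levels Nominal cylinder levels (dB), default
#'   `c(-9, -6, -3, 3, 6)`.
#' @return An object of class `us_contrast` with fields `data` (per-cylinder
#'   means), `slope`, `intercept`, `r_squared` and the underlying `fit`.
#' @export
contrast_resolution <- function(volume, rois,
                                nominal_levels = c(-9, -6, -3, 3, 6)) {
  if (length(rois) != 5 || length(nominal_levels) != 5) {
    stop_us("contrast resolution needs exactly 5 ROIs and 5 nominal levels",
            "us_invalid_roi")
  }
  means <- vapply(rois, function(r) mean(volume$data[roi_indices(volume, r)]),
                  numeric(1))
  dat <- tibble::tibble(level_db = nominal_levels, mean_gray = means)
  fit <- stats::lm(mean_gray ~ level_db, data = dat)
  sst <- sum((dat$mean_gray - mean(dat$mean_gray))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(data = dat,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 fit = fit),
            class = "us_contrast")
}

#' @export
print.us_contrast <- function(x, ...) {
  cat(sprintf("<us_contrast> slope %.3f gray/dB (r^2 = %.4f)\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' Locate a distance-marker peak
#'
#' Argmax of gray value inside the search ROI. When several voxels tie at
#' the maximum (e.g. a clipped marker), the tied voxel closest to the
#' centroid of the tied set is taken — the automated analogue of picking the
#' centre pixel by hand — with remaining ties broken by the smallest linear
#' index. A flat ROI with no peak above background + 3 SD raises an error.
#'
#' @param volume An `us_volume`.
#' @param roi A [roi_spec()] containing exactly one marker.
#' @return Named integer voxel coordinate `(i, j, k)`.
#' @export
find_marker_peak <- function(volume, roi) {
  idx <- roi_indices(volume, roi, clip = TRUE)
  vals <- volume$data[idx]
  bg <- stats::median(vals)
  if (max(vals) <= bg + 3 * stats::sd(vals)) {
    stop_us("no marker: ROI has no peak above background + 3 SD", "us_no_marker")
  }
  tied <- idx[vals == max(vals)]
  co <- arrayInd(tied, dim(volume$data))
  if (nrow(co) > 1) {
    centroid <- colMeans(co)
    d2 <- rowSums((co - matrix(centroid, nrow(co), 3, byrow = TRUE))^2)
    best <- which(d2 == min(d2))
    pick <- best[which.min(tied[best])]
  } else {
    pick <- 1
  }
  setNames(as.integer(co[pick, ]), c("i", "j", "k"))
}

#' Distance-calibration error
#'
#' Measured marker separation versus nominal: the distance error is the
#' absolute difference between the actual distance and the Euclidean
#' distance of the two marker voxels in mm (per-axis spacing applied).
#'
#' @param p1,p2 Voxel coordinates `(i, j, k)` of the two markers.
#' @param spacing Length-3 voxel spacing (mm), e.g. `volume$spacing`.
#' @param d_actual Nominal marker separation (mm): 30 axially, 50 in
#'   elevation for the default phantom.
#' @return A one-row tibble of class `us_distance` with `d_actual`,
#'   `d_measured` and `error_mm`.
#' @export
distance_error <- function(p1, p2, spacing, d_actual) {
  if (all(p1 == p2)) stop_us("marker voxels must differ", "us_invalid_roi")
  dm <- sqrt(sum(((as.numeric(p1) - as.numeric(p2)) * spacing)^2))
  structure(tibble::tibble(d_actual = d_actual, d_measured = dm,
                           error_mm = abs(d_actual - dm)),
            class = c("us_distance", "tbl_df", "tbl", "data.frame"))
}

#' Extract a line profile through a voxel
#'
#' Gray values along the axial or elevation axis through a marker peak,
#' spanning the full volume extent on that axis. Lateral profiles are not
#' supported (resolution is assessed axially and in elevation only).
#'
#' @param volume An `us_volume`.
#' @param through Voxel coordinate `(i, j, k)` the line passes through.
#' @param axis `"axial"` or `"elevation"`.
#' @return A tibble of class `us_line_profile` with `position_mm` and `gray`,
#'   plus attributes `axis` and `spacing_mm`.
#' @export
line_profile <- function(volume, through, axis = c("axial", "elevation")) {
  axis <- tryCatch(match.arg(axis), error = function(e) {
    stop_us("unsupported profile axis (use \"axial\" or \"elevation\")",
            "us_invalid_axis")
  })
  through <- as.integer(through)
  d <- dim(volume$data)
  if (any(through < 1 | through > d)) {
    stop_us("profile anchor voxel lies outside the volume", "us_roi_outside")
  }
  if (axis == "axial") {
    gray <- volume$data[, through[2], through[3]]
    sp <- volume$spacing[1]
  } else {
    gray <- volume$data[through[1], through[2], ]
    sp <- volume$spacing[3]
  }
  out <- tibble::tibble(position_mm = (seq_along(gray) - 1) * sp,
                        gray = as.numeric(gray))
  attr(out, "axis") <- axis
  attr(out, "spacing_mm") <- sp
  class(out) <- c("us_line_profile", class(out))
  out
}

#' Full width at half maximum of a line profile
#'
#' The resolution measure: the width of the marker peak at a -6 dB (half
#' amplitude) reduction of its maximum. The background floor is estimated
#' from the outer 10% of samples at each end of the profile (median per end;
#' the larger of the two is used, which is robust to an anechoic water
#' standoff at one end). The half level is background + (peak -
#' background)/2 and the two crossings are located by linear interpolation
#' between the bracketing samples on each side of the peak.
#'
#' @param profile A [line_profile()].
#' @return An object of class `us_fwhm` with `fwhm_mm`, `peak_gray`,
#'   `half_level`, `left_mm`, `right_mm`, `peak_position_mm`.
#' @export
fwhm <- function(profile) {
  g <- profile$gray
  pos <- profile$position_mm
  n <- length(g)
  k <- max(1, floor(0.1 * n))
  bg <- max(stats::median(g[seq_len(k)]), stats::median(g[n - seq_len(k) + 1]))
  ip <- which.max(g)
  peak <- g[ip]
  if (peak <= bg) {
    stop_us("profile has no peak above background", "us_no_peak")
  }
  half <- bg + (peak - bg) / 2

  cross <- function(side) {
    idx <- if (side == "left") {
      if (ip == 1) integer() else rev(seq_len(ip - 1))
    } else {
      if (ip == n) integer() else (ip + 1):n
    }
    below <- if (length(idx)) idx[which(g[idx] < half)[1]] else NA_integer_
    if (is.na(below)) {
      stop_us(sprintf("half level never crossed on the %s side (peak clipped by the volume edge)",
                      side), "us_clipped_peak")
    }
    inner <- if (side == "left") below + 1 else below - 1
    # linear interpolation between the bracketing samples
    frac <- (half - g[below]) / (g[inner] - g[below])
    pos[below] + frac * (pos[inner] - pos[below])
  }
  left <- cross("left")
  right <- cross("right")
  structure(list(fwhm_mm = right - left, peak_gray = peak, half_level = half,
                 left_mm = left, right_mm = right,
                 peak_position_mm = pos[ip],
                 axis = attr(profile, "axis")),
            class = "us_fwhm")
}

#' @export
print.us_fwhm <- function(x, ...) {
  cat(sprintf("<us_fwhm> %.3f mm (%s), peak %.0f, half level %.1f\n",
              x$fwhm_mm, x$axis %||% "?", x$peak_gray, x$half_level))
  invisible(x)
}

#' Segment the phantom surface in the mid-lateral plane
#'
#' Takes the middle YZ (axial x elevation) plane of the volume and, per
#' elevation column, locates the phantom surface as the first axial position
#' with gray at or above the threshold. With `subpixel = TRUE` (default) the
#' threshold crossing is refined by linear interpolation between the
#' bracketing pixels, removing the integer-quantization bias of the strict
#' binary-image procedure (`subpixel = FALSE` reproduces that procedure).
#' A baseline row is fixed above the shallowest surface point and the
#' perpendicular distance `f(x)` from the baseline to the surface is
#' recorded over the central 25% of elevation columns; `Df` is its forward
#' difference.
#'
#' @param volume An `us_volume`.
#' @param threshold Gray threshold for the binary surface segmentation.
#' @param baseline_frac Fraction of the elevation extent used as baseline.
#' @param baseline_offset_px Rows between the shallowest surface point and
#'   the baseline.
#' @param subpixel Logical, sub-pixel refinement of the threshold crossing.
#' @return A tibble of class `us_surface_profile` with `column` and `f_px`,
#'   plus attributes `Df`, `axial_spacing_mm`, `baseline_row`.
#' @export
surface_profile <- function(volume, threshold = 100, baseline_frac = 0.25,
                            baseline_offset_px = 10, subpixel = TRUE) {
  d <- dim(volume$data)
  mid <- ceiling(d[2] / 2)
  plane <- volume$data[, mid, ]
  pos <- vapply(seq_len(d[3]),
                function(k) surface_cross(plane[, k], threshold, subpixel),
                numeric(1))
  n <- ceiling(baseline_frac * d[3])
  start <- floor((d[3] - n) / 2) + 1
  cols <- start:(start + n - 1)
  if (anyNA(pos[cols])) {
    bad <- cols[is.na(pos[cols])]
    stop_us(paste("no suprathreshold surface in baseline column(s):",
                  paste(utils::head(bad, 10), collapse = ", ")),
            "us_no_surface")
  }
  baseline_row <- floor(min(pos[cols])) - baseline_offset_px
  f <- pos[cols] - baseline_row
  out <- tibble::tibble(column = cols, f_px = f)
  attr(out, "Df") <- diff(f)
  attr(out, "axial_spacing_mm") <- volume$spacing[1]
  attr(out, "baseline_row") <- baseline_row
  attr(out, "threshold") <- threshold
  class(out) <- c("us_surface_profile", class(out))
  out
}

#' Build a surface profile from known per-column distances
#'
#' Constructs an `us_surface_profile` directly from baseline-to-surface
#' distances in pixels, for closed-form checks of the stability statistic.
#'
#' @param f_px Numeric vector of distances (pixels).
#' @param axial_spacing_mm Axial pixel spacing (mm).
#' @return An `us_surface_profile`.
#' @export
as_surface_profile <- function(f_px, axial_spacing_mm) {
  out <- tibble::tibble(column = seq_along(f_px), f_px = f_px)
  attr(out, "Df") <- diff(f_px)
  attr(out, "axial_spacing_mm") <- axial_spacing_mm
  attr(out, "baseline_row") <- NA_integer_
  class(out) <- c("us_surface_profile", class(out))
  out
}

#' Surface-stability statistic
#'
#' Root-mean-square of the slice-to-slice derivative of the segmented
#' surface height, `RMS = sqrt(mean(Df^2))`, together with `min(Df)` and
#' `max(Df)`; all three are converted to mm by the axial pixel spacing. The
#' surface curvature is deliberately not detrended — on a curved phantom a
#' constant `Df` of 0 does not occur. The statistic quantifies slice-to-slice
#' instability (hand tremor surviving reconstruction).
#'
#' @param profile A [surface_profile()] (or [as_surface_profile()]).
#' @return A one-row tibble of class `us_stability` with `rms_mm`, `min_mm`,
#'   `max_mm` and `n`.
#' @export
stability <- function(profile) {
  Df <- attr(profile, "Df")
  if (is.null(Df) || length(Df) == 0) {
    stop_us("surface profile has an empty derivative", "us_invalid_profile")
  }
  sp <- attr(profile, "axial_spacing_mm")
  structure(tibble::tibble(rms_mm = sqrt(mean(Df^2)) * sp,
                           min_mm = min(Df) * sp,
                           max_mm = max(Df) * sp,
                           n = nrow(profile)),
            class = c("us_stability", "tbl_df", "tbl", "data.frame"))
}

#' Run all quality metrics on a volume
#'
#' Drives the five image-quality metrics with regions of interest derived
#' from the phantom ground truth: contrast-resolution slope over the five
#' cylinders, axial and elevation -6 dB FWHM through the wire at 1-cm depth,
#' axial (30 mm) and elevation (50 mm) distance-calibration errors from the
#' outermost filament pairs, and the surface-stability statistic. Metrics
#' whose targets fall outside the volume are recorded as `NA` with the
#' reason in `notes`, never silently dropped.
#'
#' @param volume An `us_volume` (origin/spacing must place the phantom
#'   coordinates, as produced by [stack_volume()] or [pnn_reconstruct()]).
#' @param phantom The `us_phantom` that was imaged (nominal geometry;
#'   injected miscalibrations are what the metrics are meant to measure).
#' @param method,movement,step_size_mm,operator Optional metadata copied
#'   into the report row.
#' @param threshold Surface-segmentation threshold for stability.
#' @return A one-row tibble (QA report row).
#' @export
run_qa <- function(volume, phantom, method = volume$method, movement = NA,
                   step_size_mm = NA, operator = NA, threshold = 100) {
  notes <- character()
  note_na <- function(metric, err) {
    notes <<- c(notes, paste0(metric, ": ", conditionMessage(err)))
    NA_real_
  }
  vox <- function(x, y, z) mm_to_voxel(volume, x, y, z)
  d <- dim(volume$data)
  inside <- function(p) all(p >= 1 & p <= d)

  # contrast: cylinder ROIs with a 1-mm wall margin, central elevation span
  contrast <- tryCatch({
    cyl <- phantom$contrast_cylinders
    kz <- round(d[3] / 2)
    hk <- max(1L, floor(d[3] * 0.4))
    hk <- max(0L, min(hk, kz - 1L, d[3] - kz))
    rois <- lapply(seq_len(nrow(cyl)), function(i) {
      ctr <- vox(cyl$x[i], cyl$y[i], 0)
      roi_spec(c(ctr[1], ctr[2], kz), half_extent = c(0, 0, hk),
               shape = "cylinder", radius_mm = cyl$radius_mm[i] - 1)
    })
    contrast_resolution(volume, rois, cyl$level_db)$slope
  }, error = function(e) note_na("contrast_resolution", e))

  # resolution: wire at 1-cm depth
  res <- tryCatch({
    w <- phantom$wire_targets[1, ]
    ctr <- vox(w$x, w$y, w$z)
    h <- pmax(1L, round(c(2 / volume$spacing[1], 2 / volume$spacing[2],
                          3 / volume$spacing[3])))
    peak <- find_marker_peak(volume, roi_spec(ctr, h))
    list(ax = fwhm(line_profile(volume, peak, "axial"))$fwhm_mm,
         el = fwhm(line_profile(volume, peak, "elevation"))$fwhm_mm)
  }, error = function(e) {
    list(ax = note_na("resolution_axial", e), el = note_na("resolution_elevation", e))
  })

  filament_error <- function(fil, d_actual, axis) {
    ords <- if (axis == "axial") order(fil$y) else order(fil$z)
    lo <- fil[ords[1], ]; hi <- fil[ords[nrow(fil)], ]
    h <- pmax(1L, round(c(3 / volume$spacing[1], 1.5 / volume$spacing[2],
                          3 / volume$spacing[3])))
    # the shallowest axial marker sits 2 mm under the bright surface band:
    # use a tighter axial window there so the band stays out of the search ROI
    h_lo <- h
    if (axis == "axial") h_lo[1] <- max(1L, round(1.7 / volume$spacing[1]))
    p1 <- find_marker_peak(volume, roi_spec(vox(lo$x, lo$y, lo$z), h_lo))
    p2 <- find_marker_peak(volume, roi_spec(vox(hi$x, hi$y, hi$z), h))
    distance_error(p1, p2, volume$spacing, d_actual)$error_mm
  }
  dist_ax <- tryCatch(
    filament_error(phantom$axial_filaments, 30, "axial"),
    error = function(e) note_na("dist_cal_axial", e))
  dist_el <- tryCatch(
    filament_error(phantom$elevation_filaments, 50, "elevation"),
    error = function(e) note_na("dist_cal_elevation", e))

  stab <- tryCatch(
    stability(surface_profile(volume, threshold = threshold)),
    error = function(e) {
      v <- note_na("stability", e)
      tibble::tibble(rms_mm = v, min_mm = v, max_mm = v, n = NA_integer_)
    })

  tibble::tibble(
    method = method, movement = movement, step_size_mm = step_size_mm,
    operator = operator,
    contrast_resolution = contrast,
    resolution_axial_mm = res$ax,
    resolution_elevation_mm = res$el,
    dist_cal_axial_mm = dist_ax,
    dist_cal_elevation_mm = dist_el,
    stability_rms_mm = stab$rms_mm,
    stability_min_mm = stab$min_mm,
    stability_max_mm = stab$max_mm,
    notes = if (length(notes)) paste(notes, collapse = "; ") else NA_character_
  )
}
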