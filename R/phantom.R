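#' Specify a digital ultrasound calibration phantom
#'
#' Builds the geometric and echogenic ground truth of a multi-purpose
#' grayscale phantom: five contrast cylinders at known nominal echo levels,
#' a 0.1-mm wire resolution target, two groups of distance-calibration
#' filaments at 10-mm spacing (spanning 30 mm axially and 50 mm in
#' elevation), and a gently curved surface under a water standoff.
#'
#' World coordinates are millimetres with `x` = lateral, `y` = axial depth
#' (positive downwards, 0 at the transducer face) and `z` = elevation (the
#' sweep direction). This axis convention is used throughout the package:
#' image rows are axial, image columns lateral, and slice index elevation.
#'
#' @param water_standoff_mm Depth of water above the phantom surface (mm).
#' @param surface_curvature Quadratic curvature coefficient of the surface
#'   depth profile along elevation (mm^-1); the surface sits at
#'   `water_standoff_mm + surface_curvature * (z - surface_vertex_z)^2`.
#'   Zero gives a perfectly flat surface.
#' @param surface_vertex_z Elevation (mm) of the shallowest surface point.
#' @param contrast_cylinders Tibble with columns `x`, `y`, `radius_mm`,
#'   `level_db`; cylinders run along the full elevation extent.
#' @param wire_targets Tibble with columns `x`, `y`, `z`, `diameter_mm`.
#' @param axial_filaments Tibble (`x`, `y`, `z`, `diameter_mm`) of the
#'   vertical distance-calibration group; must span 30 mm at 10-mm spacing.
#' @param elevation_filaments As above for the horizontal group; must span
#'   50 mm at 10-mm spacing.
#' @param extent_lateral,extent_elevation Length-2 numeric, phantom extent
#'   (mm) in the lateral and elevation directions.
#' @param background_gray Mean echo level of the phantom material (8-bit).
#' @param water_gray Mean echo level of the water standoff (8-bit).
#' @param surface_gray Peak gray value of the bright surface interface.
#' @param target_gray Gray amplitude added at the centre of wires and
#'   filaments (on top of the local background).
#' @param speckle_sigma Standard deviation of the additive gray-value noise.
#' @param contrast_map `"linear"`: cylinder gray = background +
#'   `contrast_slope` * level_db (the default, so the contrast-resolution
#'   slope is a directly recoverable generator parameter); `"amplitude"`:
#'   gray = background * 10^(level_db / 20).
#' @param contrast_slope Gray values per dB for the linear contrast map.
#' @return An object of class `us_phantom`.
#' @seealso [default_phantom()], [phantom_targets()], [surface_depth()]
#' @export
phantom_spec <- function(water_standoff_mm = 10,
                         surface_curvature = 0.0015,
                         surface_vertex_z = 40,
                         contrast_cylinders,
                         wire_targets,
                         axial_filaments,
                         elevation_filaments,
                         extent_lateral = c(0, 40),
                         extent_elevation = c(0, 80),
                         background_gray = 120,
                         water_gray = 2,
                         surface_gray = 220,
                         target_gray = 130,
                         speckle_sigma = 5,
                         contrast_map = c("linear", "amplitude"),
                         contrast_slope = 6.3) {
  contrast_map <- match.arg(contrast_map)
  stopifnot(water_standoff_mm > 0, speckle_sigma >= 0, background_gray >= 0)

  allowed_db <- c(-9, -6, -3, 3, 6)
  if (!all(contrast_cylinders$level_db %in% allowed_db)) {
    stop_us("contrast cylinder nominal levels must lie in {-9, -6, -3, +3, +6} dB",
            "us_invalid_phantom")
  }
  span <- function(v) diff(range(v))
  if (nrow(axial_filaments) > 1) {
    if (abs(span(axial_filaments$y) - 30) > 1e-9) {
      stop_us("axial filament group must span exactly 30 mm", "us_invalid_phantom")
    }
    if (any(abs(diff(sort(axial_filaments$y)) - 10) > 1e-9)) {
      stop_us("axial filament spacing must be 10 mm", "us_invalid_phantom")
    }
  }
  if (nrow(elevation_filaments) > 1) {
    if (abs(span(elevation_filaments$z) - 50) > 1e-9) {
      stop_us("elevation filament group must span exactly 50 mm", "us_invalid_phantom")
    }
    if (any(abs(diff(sort(elevation_filaments$z)) - 10) > 1e-9)) {
      stop_us("elevation filament spacing must be 10 mm", "us_invalid_phantom")
    }
  }
  if (any(c(wire_targets$diameter_mm, axial_filaments$diameter_mm,
            elevation_filaments$diameter_mm) != 0.1)) {
    stop_us("wire and filament targets must have 0.1 mm diameter", "us_invalid_phantom")
  }
  inside <- function(x, lim) all(x >= lim[1] & x <= lim[2])
  lat_ok <- inside(c(contrast_cylinders$x, wire_targets$x,
                     axial_filaments$x, elevation_filaments$x), extent_lateral)
  elev_ok <- inside(c(wire_targets$z, axial_filaments$z, elevation_filaments$z),
                    extent_elevation)
  if (!lat_ok || !elev_ok) {
    stop_us("all targets must lie inside the phantom extent", "us_invalid_phantom")
  }

  structure(
    list(
      water_standoff_mm = water_standoff_mm,
      surface_curvature = surface_curvature,
      surface_vertex_z = surface_vertex_z,
      contrast_cylinders = tibble::as_tibble(contrast_cylinders),
      wire_targets = tibble::as_tibble(wire_targets),
      axial_filaments = tibble::as_tibble(axial_filaments),
      elevation_filaments = tibble::as_tibble(elevation_filaments),
      extent_lateral = extent_lateral,
      extent_elevation = extent_elevation,
      background_gray = background_gray,
      water_gray = water_gray,
      surface_gray = surface_gray,
      target_gray = target_gray,
      speckle_sigma = speckle_sigma,
      contrast_map = contrast_map,
      contrast_slope = contrast_slope
    ),
    class = "us_phantom"
  )
}

#' Default digital phantom
#'
#' The standard phantom used throughout the package: five contrast cylinders
#' at -9, -6, -3, +3 and +6 dB, a 0.1-mm wire at 1 cm depth below the
#' surface (20 mm from the transducer face including the 10-mm water
#' standoff), four axial filaments spanning 30 mm, and six elevation
#' filaments spanning 50 mm, both at 10-mm spacing.
#'
#' @param surface_curvature Surface curvature coefficient (mm^-1); 0 gives a
#'   flat surface. See [phantom_spec()].
#' @param extent_elevation Elevation extent (mm) of the phantom.
#' @inheritParams phantom_spec
#' @param ... Further arguments passed to [phantom_spec()].
#' @return An `us_phantom` object.
#' @export
#' @examples
#' ph <- default_phantom()
#' phantom_targets(ph)
default_phantom <- function(surface_curvature = 0.0015,
                            extent_elevation = c(0, 80),
                            contrast_cylinders = tibble::tibble(
                              x = c(6, 13, 20, 27, 34), y = 30, radius_mm = 3,
                              level_db = c(-9, -6, -3, 3, 6)
                            ),
                            wire_targets = tibble::tibble(
                              x = 25, y = 20, z = 30, diameter_mm = 0.1
                            ),
                            axial_filaments = tibble::tibble(
                              x = 10, y = c(12, 22, 32, 42), z = 40,
                              diameter_mm = 0.1
                            ),
                            elevation_filaments = tibble::tibble(
                              x = 30, y = 25, z = c(5, 15, 25, 35, 45, 55),
                              diameter_mm = 0.1
                            ),
                            ...) {
  phantom_spec(
    surface_curvature = surface_curvature,
    extent_elevation = extent_elevation,
    contrast_cylinders = contrast_cylinders,
    wire_targets = wire_targets,
    axial_filaments = axial_filaments,
    elevation_filaments = elevation_filaments,
    ...
  )
}

#' Surface depth of the phantom
#'
#' Axial depth (mm from the transducer face) of the phantom surface at given
#' lateral and elevation world coordinates. Vectorised; `lateral` and
#' `elevation` may be equal-shaped matrices.
#'
#' @param phantom An `us_phantom`.
#' @param lateral,elevation World coordinates (mm).
#' @return Depths, same shape as the inputs.
#' @export
surface_depth <- function(phantom, lateral, elevation) {
  phantom$water_standoff_mm +
    phantom$surface_curvature * (elevation - phantom$surface_vertex_z)^2 +
    0 * lateral
}

#' Ground-truth target table
#'
#' Every point target and cylinder of the phantom with its exact world
#' coordinates, for ground-truth-driven region-of-interest placement and
#' peak-recovery checks.
#'
#' @param phantom An `us_phantom`.
#' @return A tibble with columns `group`, `id`, `x`, `y`, `z`, `level_db`,
#'   `diameter_mm`, `radius_mm`.
#' @export
phantom_targets <- function(phantom) {
  cyl <- phantom$contrast_cylinders
  dplyr::bind_rows(
    tibble::tibble(group = "wire", id = seq_len(nrow(phantom$wire_targets)),
                   x = phantom$wire_targets$x, y = phantom$wire_targets$y,
                   z = phantom$wire_targets$z,
                   diameter_mm = phantom$wire_targets$diameter_mm),
    tibble::tibble(group = "axial_filament",
                   id = seq_len(nrow(phantom$axial_filaments)),
                   x = phantom$axial_filaments$x, y = phantom$axial_filaments$y,
                   z = phantom$axial_filaments$z,
                   diameter_mm = phantom$axial_filaments$diameter_mm),
    tibble::tibble(group = "elevation_filament",
                   id = seq_len(nrow(phantom$elevation_filaments)),
                   x = phantom$elevation_filaments$x,
                   y = phantom$elevation_filaments$y,
                   z = phantom$elevation_filaments$z,
                   diameter_mm = phantom$elevation_filaments$diameter_mm),
    tibble::tibble(group = "cylinder", id = seq_len(nrow(cyl)),
                   x = cyl$x, y = cyl$y, z = NA_real_,
                   level_db = cyl$level_db, radius_mm = cyl$radius_mm)
  )
}

#' Inject a distance-scale miscalibration into the phantom
#'
#' Rescales the filament group coordinates about the group's first marker,
#' so the rendered marker separation differs from the nominal 30 mm (axial)
#' or 50 mm (elevation) span by a known amount. Used to verify that the
#' distance-calibration metric recovers an injected discrepancy.
#'
#' @param phantom An `us_phantom`.
#' @param axial_scale,elevation_scale Multiplicative scale factors applied to
#'   the axial filament depths / elevation filament positions.
#' @return The modified `us_phantom`.
#' @export
#' @examples
#' # displace the 30-mm axial span by +1.79 mm
#' ph <- miscalibrate_phantom(default_phantom(), axial_scale = 1 + 1.79 / 30)
miscalibrate_phantom <- function(phantom, axial_scale = 1, elevation_scale = 1) {
  af <- phantom$axial_filaments
  y0 <- min(af$y)
  phantom$axial_filaments$y <- y0 + (af$y - y0) * axial_scale
  ef <- phantom$elevation_filaments
  z0 <- min(ef$z)
  phantom$elevation_filaments$z <- z0 + (ef$z - z0) * elevation_scale
  phantom
}

#' Gaussian beam profile of the imaging system
#'
#' A separable Gaussian point-spread function parameterised by its full
#' widths at half maximum. The elevation width is the slice thickness, and
#' must exceed the 0.1-mm wire diameter. Defaults correspond to typical
#' 10-MHz linear-probe performance at the focus.
#'
#' @param axial_fwhm,lateral_fwhm,elevation_fwhm Beam widths (mm).
#' @return An object of class `us_beam`.
#' @export
beam_profile <- function(axial_fwhm = 0.33, lateral_fwhm = 0.40,
                         elevation_fwhm = 1.02) {
  if (any(c(axial_fwhm, lateral_fwhm, elevation_fwhm) <= 0)) {
    stop_us("beam widths must be positive", "us_invalid_beam")
  }
  if (elevation_fwhm <= 0.1) {
    stop_us("elevation beam width (slice thickness) must exceed the 0.1 mm wire diameter",
            "us_invalid_beam")
  }
  structure(list(axial_fwhm = axial_fwhm, lateral_fwhm = lateral_fwhm,
                 elevation_fwhm = elevation_fwhm), class = "us_beam")
}

#' 2D image geometry of the scanner
#'
#' @param depth_cm Imaging depth setting (cm); rows are derived from it. The
#'   default window (4.3 cm, i.e. a nominal 4-cm setting with margin) covers
#'   the 30-mm axial marker group under the 10-mm water standoff; elevation
#'   distance calibration uses a 5-cm window.
#' @param pixel_spacing_axial,pixel_spacing_lateral Pixel spacings (mm),
#'   must lie in `[0.08, 0.30]`.
#' @param width_mm Lateral field-of-view width (mm).
#' @param fps Frame rate (frames per second).
#' @return An object of class `us_geometry` with `rows` and `cols` fields.
#' @export
image_geometry <- function(depth_cm = 4.3, pixel_spacing_axial = 0.12,
                           pixel_spacing_lateral = 0.12, width_mm = 40,
                           fps = 10) {
  sp <- c(pixel_spacing_axial, pixel_spacing_lateral)
  if (any(sp < 0.08 | sp > 0.30)) {
    stop_us("pixel spacings must lie within [0.08, 0.30] mm", "us_invalid_geometry")
  }
  stopifnot(depth_cm > 0, width_mm > 0, fps > 0)
  structure(
    list(rows = as.integer(round(depth_cm * 10 / pixel_spacing_axial)),
         cols = as.integer(round(width_mm / pixel_spacing_lateral)),
         pixel_spacing_axial = pixel_spacing_axial,
         pixel_spacing_lateral = pixel_spacing_lateral,
         depth_cm = depth_cm, fps = fps),
    class = "us_geometry"
  )
}

#' Hand-tremor model for freehand sweeps
#'
#' Freehand probe motion is the ideal sweep plus, on every axis, a
#' band-limited physiological tremor oscillation (random phase, single band
#' around 8-12 Hz) and a slowly drifting random walk. `amplitude_mm` is the
#' RMS displacement of the oscillation per axis, so the sample standard
#' deviation of positions about the mean path recovers it directly. Zero
#' amplitudes and walk reproduce an ideal sweep.
#'
#' @param amplitude_mm RMS tremor oscillation amplitude per axis (mm),
#'   length 1 or 3 (lateral, axial, elevation).
#' @param band_hz Tremor frequency (Hz).
#' @param walk_sd_mm Random-walk increment scale (mm per sqrt(s)).
#' @param angular_jitter_deg RMS angular oscillation per axis (degrees).
#' @return An object of class `us_tremor`.
#' @export
tremor_model <- function(amplitude_mm = 0.3, band_hz = 9, walk_sd_mm = 0.05,
                         angular_jitter_deg = 0.5) {
  amplitude_mm <- rep_len(amplitude_mm, 3)
  if (any(amplitude_mm < 0) || walk_sd_mm < 0 || angular_jitter_deg < 0) {
    stop_us("tremor amplitudes must be non-negative", "us_invalid_tremor")
  }
  structure(list(amplitude_mm = amplitude_mm, band_hz = band_hz,
                 walk_sd_mm = walk_sd_mm,
                 angular_jitter_deg = angular_jitter_deg),
            class = "us_tremor")
}

#' Electromagnetic tracking noise model
#'
#' Defaults follow the published specification of a 6DOF electromagnetic
#' sensor: 0.48 mm position RMS (3D), 0.30 degree orientation RMS, 40 Hz
#' measurement rate, and a -30 ms offset between the tracking clock and the
#' image clock.
#'
#' @param position_rms_mm 3D RMS position error (per-axis noise is
#'   `position_rms_mm / sqrt(3)`).
#' @param orientation_rms_deg 3D RMS orientation error (degrees).
#' @param measurement_rate_hz Tracking sample rate (Hz).
#' @param temporal_offset_ms Tracking clock minus image clock (ms).
#' @return An object of class `us_tracking_noise`.
#' @export
tracking_noise <- function(position_rms_mm = 0.48, orientation_rms_deg = 0.30,
                           measurement_rate_hz = 40, temporal_offset_ms = -30) {
  stopifnot(position_rms_mm >= 0, orientation_rms_deg >= 0,
            measurement_rate_hz > 0)
  structure(list(position_rms_mm = position_rms_mm,
                 orientation_rms_deg = orientation_rms_deg,
                 measurement_rate_hz = measurement_rate_hz,
                 temporal_offset_ms = temporal_offset_ms),
            class = "us_tracking_noise")
}

#' Acquisition protocol configuration
#'
#' Mirrors the protocol variables of a motorized-rail or freehand sweep:
#' stepwise motion advances by `step_size_mm` (restricted to 0.1, 0.2, 0.5 or
#' 1.0 mm) with a 0.5-s dwell per step; continuous motion derives its
#' effective step size as `velocity / fps`; compound imaging (stepwise only)
#' averages `n_compound` frames per pose. Freehand sweeps move at `velocity`
#' with tremor and cannot use compounding.
#'
#' @param method `"motorized"` or `"freehand"`.
#' @param movement `"stepwise"` or `"continuous"` (motorized);
#'   freehand always uses its own sweep.
#' @param step_size_mm Elevation step (mm) for stepwise motion.
#' @param velocity Sweep velocity (mm/s) for continuous/freehand motion.
#' @param compounding Logical, average multiple frames per pose.
#' @param n_compound Frames averaged per pose when compounding.
#' @param dwell_s Settle time between stepwise steps (s).
#' @param sweep_length_mm Total elevation travel (mm).
#' @return An object of class `us_config`.
#' @export
acquisition_config <- function(method = c("motorized", "freehand"),
                               movement = NULL, step_size_mm = NULL,
                               velocity = NULL, compounding = FALSE,
                               n_compound = 5, dwell_s = 0.5,
                               sweep_length_mm = 60) {
  method <- match.arg(method)
  if (method == "freehand") {
    movement <- "freehand"
    if (isTRUE(compounding)) {
      stop_us("compound imaging is only available for motorized stepwise sweeps",
              "us_invalid_config")
    }
    velocity <- velocity %||% 2
  } else {
    movement <- match.arg(movement, c("stepwise", "continuous"))
    if (movement == "stepwise") {
      allowed <- c(0.1, 0.2, 0.5, 1.0)
      if (is.null(step_size_mm) || !any(abs(step_size_mm - allowed) < 1e-9)) {
        stop_us("stepwise step size must be one of 0.1, 0.2, 0.5, 1.0 mm",
                "us_invalid_config")
      }
    } else {
      if (is.null(velocity) || velocity <= 0) {
        stop_us("continuous movement requires a positive velocity", "us_invalid_config")
      }
      if (isTRUE(compounding)) {
        stop_us("compound imaging is only available for motorized stepwise sweeps",
                "us_invalid_config")
      }
    }
  }
  stopifnot(sweep_length_mm > 0, dwell_s >= 0, n_compound >= 1)
  structure(list(method = method, movement = movement,
                 step_size_mm = step_size_mm, velocity = velocity,
                 compounding = isTRUE(compounding), n_compound = n_compound,
                 dwell_s = dwell_s, sweep_length_mm = sweep_length_mm),
            class = "us_config")
}

#' @export
print.us_phantom <- function(x, ...) {
  cat("<us_phantom>\n")
  cat("  standoff:", x$water_standoff_mm, "mm; surface curvature:",
      x$surface_curvature, "mm^-1\n")
  cat("  cylinders:", nrow(x$contrast_cylinders),
      "(", paste(x$contrast_cylinders$level_db, collapse = ", "), "dB )\n")
  cat("  filaments:", nrow(x$axial_filaments), "axial /",
      nrow(x$elevation_filaments), "elevation; wires:",
      nrow(x$wire_targets), "\n")
  invisible(x)
}

#' @export
print.us_config <- function(x, ...) {
  cat("<us_config>", x$method, x$movement,
      if (!is.null(x$step_size_mm)) paste0("step ", x$step_size_mm, " mm"),
      if (!is.null(x$velocity)) paste0("v ", x$velocity, " mm/s"),
      if (x$compounding) sprintf("compound x%d", x$n_compound), "\n")
  invisible(x)
}
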