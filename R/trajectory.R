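#' Probe pose
#'
#' A single probe pose: position of the image origin (top-left pixel centre)
#' in world millimetres and a small-angle orientation triple in degrees.
#'
#' @param x,y,z Lateral, axial and elevation position (mm).
#' @param rx,ry,rz Rotations about the lateral, axial and elevation axes
#'   (degrees).
#' @param t Timestamp (s).
#' @return A one-row pose tibble.
#' @export
probe_pose <- function(x = 0, y = 0, z = 0, rx = 0, ry = 0, rz = 0, t = 0) {
  tibble::tibble(t = t, x = x, y = y, z = z, rx = rx, ry = ry, rz = rz)
}

validate_trajectory <- function(traj) {
  need <- c("t", "x", "y", "z", "rx", "ry", "rz")
  if (!all(need %in% names(traj))) {
    stop_us(paste("trajectory needs columns", paste(need, collapse = ", ")),
            "us_invalid_trajectory")
  }
  if (nrow(traj) > 1 && any(diff(traj$t) <= 0)) {
    stop_us("trajectory timestamps must be strictly increasing",
            "us_invalid_trajectory")
  }
  invisible(traj)
}

#' Motorized rail trajectory
#'
#' Poses of an ideal rail-mounted sweep: exact elevation increments with zero
#' lateral, axial and angular deviation. Stepwise motion advances by the
#' configured step size with one dwell interval between poses; continuous
#' motion is sampled at the frame rate, so the effective step size is
#' `velocity / fps`.
#'
#' @param config An [acquisition_config()] with `method = "motorized"`.
#' @param geom An [image_geometry()] (supplies the frame rate).
#' @return A pose tibble (`t, x, y, z, rx, ry, rz`).
#' @export
#' @examples
#' cfg <- acquisition_config("motorized", "stepwise", step_size_mm = 0.5,
#'                           sweep_length_mm = 30)
#' nrow(motorized_trajectory(cfg, image_geometry()))  # 61 poses
motorized_trajectory <- function(config, geom) {
  if (config$method != "motorized") {
    stop_us("motorized_trajectory requires a motorized configuration",
            "us_invalid_config")
  }
  if (config$movement == "stepwise") {
    z <- seq(0, config$sweep_length_mm, by = config$step_size_mm)
    t <- (seq_along(z) - 1) * config$dwell_s
  } else {
    dt <- 1 / geom$fps
    t_end <- config$sweep_length_mm / config$velocity
    t <- seq(0, t_end, by = dt)
    z <- config$velocity * t
  }
  tibble::tibble(t = t, x = 0, y = 0, z = z, rx = 0, ry = 0, rz = 0)
}

#' Freehand sweep trajectory
#'
#' Simulates a hand-held sweep: monotone mean elevation progress at the
#' configured velocity plus band-limited tremor (an RMS-calibrated sinusoid
#' with random phase per axis, plus a drifting random walk) on all three
#' position axes and the three orientation angles. Zero tremor amplitudes
#' reduce the path to a motorized-like ideal sweep. Deterministic given
#' `seed`.
#'
#' @param config An [acquisition_config()] with `method = "freehand"`.
#' @param tremor A [tremor_model()].
#' @param geom An [image_geometry()] (supplies the frame rate).
#' @param seed Integer RNG seed; `NULL` uses the current RNG stream.
#' @param start_mm Elevation (mm) at which the sweep starts; a small margin
#'   keeps tremor excursions inside the phantom extent.
#' @return A pose tibble.
#' @export
freehand_trajectory <- function(config, tremor = tremor_model(), geom,
                                seed = NULL, start_mm = 2) {
  if (config$method != "freehand") {
    stop_us("freehand_trajectory requires a freehand configuration",
            "us_invalid_config")
  }
  dt <- 1 / geom$fps
  t_end <- config$sweep_length_mm / config$velocity
  t <- seq(0, t_end, by = dt)
  n <- length(t)
  with_seed_maybe(seed, {
    osc <- function(rms) {
      if (rms == 0) return(numeric(n))
      rms * sqrt(2) * sin(2 * pi * tremor$band_hz * t + stats::runif(1, 0, 2 * pi))
    }
    walk <- function(sd_mm) {
      if (sd_mm == 0) return(numeric(n))
      cumsum(stats::rnorm(n, 0, sd_mm * sqrt(dt)))
    }
    a <- tremor$amplitude_mm
    tibble::tibble(
      t = t,
      x = osc(a[1]) + walk(tremor$walk_sd_mm),
      y = osc(a[2]) + walk(tremor$walk_sd_mm),
      z = start_mm + config$velocity * t + osc(a[3]) + walk(tremor$walk_sd_mm),
      rx = osc(tremor$angular_jitter_deg),
      ry = osc(tremor$angular_jitter_deg),
      rz = osc(tremor$angular_jitter_deg)
    )
  })
}

#' Temporal-calibration sweep
#'
#' A sweep with a slow, deliberate elevation oscillation ("bobbing" the
#' probe) superimposed on the mean progress. A constant-velocity sweep
#' leaves the clock lag between tracking and imaging unidentifiable —
#' shifting a linear ramp only adds a constant — so temporal calibration is
#' performed on a sweep with recognisable velocity variation, as done in
#' practice before a freehand acquisition. The oscillation is slow enough to
#' be representable at the frame rate.
#'
#' @param config A freehand [acquisition_config()].
#' @param geom An [image_geometry()].
#' @param bob_amplitude_mm Amplitude of the elevation oscillation (mm).
#' @param bob_hz Oscillation frequency (Hz); keep well below `fps / 2`.
#' @param start_mm Elevation at which the sweep starts (mm).
#' @return A pose tibble.
#' @export
calibration_trajectory <- function(config, geom, bob_amplitude_mm = 2,
                                   bob_hz = 0.5, start_mm = 4) {
  dt <- 1 / geom$fps
  t <- seq(0, config$sweep_length_mm / config$velocity, by = dt)
  tibble::tibble(
    t = t,
    x = 0, y = 0,
    z = start_mm + config$velocity * t +
      bob_amplitude_mm * sin(2 * pi * bob_hz * t),
    rx = 0, ry = 0, rz = 0
  )
}

#' Perturb a trajectory with a per-pose axial random walk
#'
#' Adds cumulative Gaussian increments to the axial (depth) coordinate of an
#' existing trajectory: pose k receives `sum of k increments ~ N(0, sd)`.
#' This injects a known per-slice surface-height jitter into rendered
#' volumes, the ground truth for stability-recovery experiments (the
#' slice-to-slice surface derivative then has RMS `sd_increment_mm`).
#'
#' @param trajectory A pose tibble.
#' @param sd_increment_mm Standard deviation of each axial increment (mm).
#' @param seed Integer RNG seed.
#' @return The perturbed trajectory.
#' @export
perturb_axial <- function(trajectory, sd_increment_mm, seed = NULL) {
  validate_trajectory(trajectory)
  with_seed_maybe(seed, {
    trajectory$y <- trajectory$y +
      cumsum(stats::rnorm(nrow(trajectory), 0, sd_increment_mm))
  })
  trajectory
}

#' Simulate electromagnetic tracking of a trajectory
#'
#' Resamples the true probe path at the tracker's measurement rate, adds
#' i.i.d. Gaussian noise per axis (position per-axis sigma =
#' `position_rms_mm / sqrt(3)` so the 3D error RMS matches the sensor
#' specification, likewise for orientation), and shifts the timestamps by the
#' temporal offset of the tracking clock relative to the image clock.
#'
#' @param trajectory The true pose tibble.
#' @param noise A [tracking_noise()].
#' @param seed Integer RNG seed.
#' @return A tracking tibble (`t, x, y, z, rx, ry, rz`) on the tracker clock.
#' @export
simulate_tracking <- function(trajectory, noise = tracking_noise(),
                              seed = NULL) {
  validate_trajectory(trajectory)
  if (nrow(trajectory) == 0) {
    stop_us("trajectory must be nonempty", "us_invalid_trajectory")
  }
  ts <- seq(min(trajectory$t), max(trajectory$t),
            by = 1 / noise$measurement_rate_hz)
  interp <- function(col) {
    if (nrow(trajectory) == 1) return(rep(trajectory[[col]], length(ts)))
    stats::approx(trajectory$t, trajectory[[col]], xout = ts)$y
  }
  out <- tibble::tibble(
    t = ts + noise$temporal_offset_ms / 1000,
    x = interp("x"), y = interp("y"), z = interp("z"),
    rx = interp("rx"), ry = interp("ry"), rz = interp("rz")
  )
  sp <- noise$position_rms_mm / sqrt(3)
  so <- noise$orientation_rms_deg / sqrt(3)
  if (sp > 0 || so > 0) {
    n <- nrow(out)
    with_seed_maybe(seed, {
      out$x <- out$x + stats::rnorm(n, 0, sp)
      out$y <- out$y + stats::rnorm(n, 0, sp)
      out$z <- out$z + stats::rnorm(n, 0, sp)
      out$rx <- out$rx + stats::rnorm(n, 0, so)
      out$ry <- out$ry + stats::rnorm(n, 0, so)
      out$rz <- out$rz + stats::rnorm(n, 0, so)
    })
  }
  out
}
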