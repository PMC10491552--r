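# Forward image model: a separable-Gaussian beam samples the phantom on the
# (rotated, translated) imaging plane. Rows are axial, columns lateral.

rotation_matrix <- function(rx, ry, rz) {
  # degrees; R = Rz %*% Ry %*% Rx acting on image-plane coordinates
  d <- pi / 180
  cx <- cos(rx * d); sx <- sin(rx * d)
  cy <- cos(ry * d); sy <- sin(ry * d)
  cz <- cos(rz * d); sz <- sin(rz * d)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

as_pose <- function(pose) {
  if (is.data.frame(pose)) pose <- as.list(pose[1, ])
  for (f in c("x", "y", "z", "rx", "ry", "rz")) pose[[f]] <- pose[[f]] %||% 0
  pose
}

#' Render a 2D ultrasound frame of the phantom
#'
#' Forward model standing in for the scanner imaging chain. The phantom
#' interior carries the background gray, water above the surface is nearly
#' anechoic, and the surface is a bright interface band with the axial beam
#' width. Contrast cylinders take their gray from the configured dB-to-gray
#' map; wires and filaments are rendered as the separable Gaussian beam
#' response centred on their intersection with the (translated and rotated)
#' imaging plane. Additive zero-mean Gaussian speckle of scale
#' `phantom$speckle_sigma` is applied before clipping to 8-bit `[0, 255]`.
#' Deterministic given `seed`.
#'
#' @param phantom An [phantom_spec()] object.
#' @param pose A one-row pose tibble or named list ([probe_pose()]).
#' @param beam A [beam_profile()].
#' @param geom An [image_geometry()].
#' @param seed Integer RNG seed for the speckle; `NULL` uses the current
#'   stream.
#' @param speckle Logical; `FALSE` renders noise-free.
#' @return An integer matrix (`geom$rows` x `geom$cols`) of 8-bit gray.
#' @export
render_frame <- function(phantom, pose, beam, geom, seed = NULL,
                         speckle = TRUE) {
  pose <- as_pose(pose)
  ez <- phantom$extent_elevation
  if (pose$z < ez[1] || pose$z > ez[2]) {
    stop_us(sprintf("pose elevation %.2f mm lies outside the phantom extent [%g, %g]",
                    pose$z, ez[1], ez[2]), "us_pose_outside")
  }
  nr <- geom$rows; nc <- geom$cols
  yi <- (seq_len(nr) - 1) * geom$pixel_spacing_axial    # image-plane axial mm
  xj <- (seq_len(nc) - 1) * geom$pixel_spacing_lateral  # image-plane lateral mm
  R <- rotation_matrix(pose$rx, pose$ry, pose$rz)
  p <- c(pose$x, pose$y, pose$z)

  # world coordinates of each pixel: w = p + R %*% (x, y, 0)
  wx <- outer(R[1, 2] * yi, R[1, 1] * xj, "+") + p[1]
  wy <- outer(R[2, 2] * yi, R[2, 1] * xj, "+") + p[2]
  wz <- outer(R[3, 2] * yi, R[3, 1] * xj, "+") + p[3]

  sdp <- surface_depth(phantom, wx, wz)
  img <- ifelse(wy >= sdp, phantom$background_gray, phantom$water_gray)

  cyl <- phantom$contrast_cylinders
  if (nrow(cyl) > 0) {
    for (i in seq_len(nrow(cyl))) {
      gray <- cylinder_gray(phantom, cyl$level_db[i])
      inside <- (wx - cyl$x[i])^2 + (wy - cyl$y[i])^2 <= cyl$radius_mm[i]^2
      img[inside] <- gray
    }
  }

  sa <- fwhm_to_sigma(beam$axial_fwhm)
  sl <- fwhm_to_sigma(beam$lateral_fwhm)
  se <- fwhm_to_sigma(beam$elevation_fwhm)

  # bright surface interface with the axial beam width
  img <- img + (phantom$surface_gray - img) * exp(-(wy - sdp)^2 / (2 * sa^2))

  # point targets: wire + filaments, expressed in image-plane coordinates
  pts <- dplyr::bind_rows(
    phantom$wire_targets[c("x", "y", "z")],
    phantom$axial_filaments[c("x", "y", "z")],
    phantom$elevation_filaments[c("x", "y", "z")]
  )
  if (nrow(pts) > 0) {
    Rt <- t(R)
    for (i in seq_len(nrow(pts))) {
      q <- Rt %*% (c(pts$x[i], pts$y[i], pts$z[i]) - p)
      if (abs(q[3]) > 5 * se) next
      amp <- phantom$target_gray * exp(-q[3]^2 / (2 * se^2))
      img <- img + amp * (exp(-(yi - q[2])^2 / (2 * sa^2)) %o%
                            exp(-(xj - q[1])^2 / (2 * sl^2)))
    }
  }

  if (speckle && phantom$speckle_sigma > 0) {
    img <- img + with_seed_maybe(seed,
      matrix(stats::rnorm(nr * nc, 0, phantom$speckle_sigma), nr, nc))
  }
  m <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nr, nc)
  m
}

# dB -> 8-bit gray mapping of the contrast cylinders
cylinder_gray <- function(phantom, level_db) {
  if (phantom$contrast_map == "linear") {
    phantom$background_gray + phantom$contrast_slope * level_db
  } else {
    phantom$background_gray * 10^(level_db / 20)
  }
}

#' Frame stream container
#'
#' An ordered set of 8-bit frames with timestamps and the geometry they were
#' rendered with.
#'
#' @param frames List of equal-sized integer matrices.
#' @param t Numeric timestamps (s), strictly increasing.
#' @param geom The [image_geometry()] of the frames.
#' @return An object of class `us_frames`.
#' @export
frame_stream <- function(frames, t, geom) {
  if (length(frames) < 2) {
    stop_us("a frame stream needs at least 2 frames", "us_invalid_frames")
  }
  if (length(frames) != length(t)) {
    stop_us("frames and timestamps differ in length", "us_invalid_frames")
  }
  if (any(diff(t) <= 0)) {
    stop_us("frame timestamps must be strictly increasing", "us_invalid_frames")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_us("all frames must share the same shape", "us_ragged_frames")
  }
  structure(list(frames = frames, t = t, geom = geom), class = "us_frames")
}

#' @export
print.us_frames <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<us_frames> %d frames of %d x %d, %.2f s span\n",
              length(x$frames), d[1], d[2], diff(range(x$t))))
  invisible(x)
}

#' @export
length.us_frames <- function(x) length(x$frames)

#' Acquire a sweep of the phantom
#'
#' Runs the full acquisition simulation: builds the trajectory implied by the
#' configuration (or uses a supplied one), renders one frame per pose, and
#' for freehand sweeps also simulates the electromagnetic tracking stream.
#' With compound imaging each stored frame is the pixel-wise mean of
#' `n_compound` renders at the identical pose (speckle averaging),
#' re-quantized to 8 bits.
#'
#' @param phantom An [phantom_spec()] object.
#' @param config An [acquisition_config()].
#' @param beam A [beam_profile()].
#' @param geom An [image_geometry()].
#' @param tremor A [tremor_model()] (freehand only).
#' @param noise A [tracking_noise()] (freehand only).
#' @param seed Integer master seed; all per-frame speckle and tracking noise
#'   derive from it, so identical `(config, seed)` give bit-identical
#'   streams.
#' @param trajectory Optional pre-computed pose tibble overriding the
#'   configuration's ideal trajectory (e.g. a perturbed one from
#'   [perturb_axial()]).
#' @param tracking_from Optional pose tibble that the simulated tracking
#'   observes instead of `trajectory` (used to model motion the tracker does
#'   not see).
#' @return A list of class `us_acquisition` with elements `frames`
#'   ([frame_stream()]), `tracking` (tibble or `NULL` for motorized sweeps),
#'   `trajectory`, `config` and `seed`.
#' @export
acquire <- function(phantom, config, beam = beam_profile(),
                    geom = image_geometry(), tremor = tremor_model(),
                    noise = tracking_noise(), seed = 1, trajectory = NULL,
                    tracking_from = NULL) {
  seeds <- derive_seeds(seed, 3)
  if (is.null(trajectory)) {
    trajectory <- if (config$method == "motorized") {
      motorized_trajectory(config, geom)
    } else {
      freehand_trajectory(config, tremor, geom, seed = seeds[1])
    }
  }
  validate_trajectory(trajectory)
  n <- nrow(trajectory)
  n_render <- if (config$compounding) config$n_compound else 1L
  fseeds <- derive_seeds(seeds[2], n * n_render)
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    pose <- trajectory[k, ]
    if (n_render == 1L) {
      frames[[k]] <- render_frame(phantom, pose, beam, geom,
                                  seed = fseeds[k])
    } else {
      acc <- 0
      for (r in seq_len(n_render)) {
        acc <- acc + render_frame(phantom, pose, beam, geom,
                                  seed = fseeds[(k - 1) * n_render + r])
      }
      m <- acc / n_render
      frames[[k]] <- matrix(as.integer(pmin(pmax(round(m), 0), 255)),
                            nrow(m), ncol(m))
    }
  }
  tracking <- NULL
  if (config$method == "freehand") {
    tracking <- simulate_tracking(tracking_from %||% trajectory, noise,
                                  seed = seeds[3])
  }
  structure(list(frames = frame_stream(frames, trajectory$t, geom),
                 tracking = tracking, trajectory = trajectory,
                 config = config, seed = seed),
            class = "us_acquisition")
}
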