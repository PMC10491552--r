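test_that("PNN degenerates to stacking on an ideal sweep at voxel pitch", {
  v <- 0.12
  geom <- small_geom(spacing = v, width_mm = 4, depth_cm = 2)
  ph <- quiet_phantom(surface_curvature = 0)
  cfg <- acquisition_config("freehand", velocity = v * geom$fps,
                            sweep_length_mm = 6)
  traj <- freehand_trajectory(cfg, tremor_model(0, walk_sd_mm = 0,
                                                angular_jitter_deg = 0),
                              geom, seed = 1, start_mm = 12)
  acq <- acquire(ph, cfg, beam_profile(), geom, seed = 1, trajectory = traj,
                 noise = tracking_noise(position_rms_mm = 0,
                                        orientation_rms_deg = 0,
                                        temporal_offset_ms = 0))
  vol_pnn <- pnn_reconstruct(acq$frames, acq$tracking,
                             pnn_config(voxel_spacing = v, fill_distance = 3))
  vol_stack <- stack_volume(acq$frames, v, origin_elevation = 12)
  expect_equal(dim(vol_pnn), dim(vol_stack))
  expect_identical(as.integer(vol_pnn$data), as.integer(vol_stack$data))
})

test_that("maximum compounding keeps the brightest deposit", {
  geom <- small_geom(spacing = 0.1, width_mm = 0.5, depth_cm = 0.1)
  # two frames at the same pose depositing 10 then 30 into the same voxels
  f1 <- matrix(10L, geom$rows, geom$cols)
  f2 <- matrix(30L, geom$rows, geom$cols)
  fr <- frame_stream(list(f1, f2), t = c(0, 0.1), geom)
  trk <- tibble::tibble(t = c(-0.1, 0.2), x = 0, y = 0, z = 0,
                        rx = 0, ry = 0, rz = 0)
  vol <- pnn_reconstruct(fr, trk, pnn_config(voxel_spacing = 0.1,
                                             fill_distance = 0))
  expect_true(all(vol$data[vol$data > 0] == 30))
})

test_that("adding frames can never lower a voxel (max-compounding monotone)", {
  geom <- small_geom(spacing = 0.1, width_mm = 1, depth_cm = 0.2)
  set.seed(42)
  mk <- function() matrix(sample(0:255, geom$rows * geom$cols, TRUE),
                          geom$rows, geom$cols)
  frames3 <- list(mk(), mk(), mk())
  trk <- tibble::tibble(t = c(-1, 3), x = 0, y = 0, z = c(0, 0.08),
                        rx = 0, ry = 0, rz = 0)
  fr2 <- frame_stream(frames3[1:2], t = c(0, 1), geom)
  fr3 <- frame_stream(frames3, t = c(0, 1, 2), geom)
  v2 <- pnn_reconstruct(fr2, trk, pnn_config(0.1, 0))
  v3 <- pnn_reconstruct(fr3, trk, pnn_config(0.1, 0))
  common <- pmin(dim(v2)[3], dim(v3)[3])
  expect_true(all(v3$data[, , seq_len(common)] >=
                    v2$data[, , seq_len(common)]))
})

test_that("PNN equals the brute-force deposit-and-fill oracle on toy grids", {
  # hand-built streams of single-row frames against an exhaustive oracle
  for (seed in 1:25) {
    set.seed(seed)
    v <- 1
    n_fr <- sample(3:5, 1)
    cols <- sample(4:6, 1)
    geom <- image_geometry(depth_cm = 0.03, pixel_spacing_axial = 0.3,
                           pixel_spacing_lateral = 0.3,
                           width_mm = cols * 0.3, fps = 1)
    frames <- lapply(seq_len(n_fr), function(i) {
      matrix(sample(0:255, geom$rows * geom$cols, TRUE),
             geom$rows, geom$cols)
    })
    zs <- cumsum(runif(n_fr, 0.4, 2.2))
    fr <- frame_stream(frames, t = seq_len(n_fr), geom)
    trk <- tibble::tibble(t = c(0, n_fr + 1), x = 0, y = 0,
                          z = c(zs[1], zs[n_fr]), rx = 0, ry = 0, rz = 0)
    # linear pose interpolation reproduces arbitrary z spacing only if the
    # timestamps match; feed exact per-frame tracking samples instead
    trk <- tibble::tibble(t = seq_len(n_fr), x = 0, y = 0, z = zs,
                          rx = 0, ry = 0, rz = 0)
    fd <- sample(0:3, 1)
    vol <- pnn_reconstruct(fr, trk, pnn_config(voxel_spacing = v,
                                               fill_distance = fd))

    # oracle input: every pixel as a world point
    pts <- NULL; vals <- NULL
    yi <- (seq_len(geom$rows) - 1) * geom$pixel_spacing_axial
    xj <- (seq_len(geom$cols) - 1) * geom$pixel_spacing_lateral
    for (k in seq_len(n_fr)) {
      g <- expand.grid(y = yi, x = xj)
      pts <- rbind(pts, cbind(g$y, g$x, zs[k]))
      vals <- c(vals, as.vector(frames[[k]]))
    }
    oracle <- brute_pnn(pts, vals, dim(vol$data), vol$origin, v, fd)
    expect_equal(unname(vol$data), unname(oracle),
                 label = sprintf("seed %d", seed))
  }
})

test_that("frames without bracketing tracking samples are dropped with a message", {
  geom <- small_geom(spacing = 0.1, width_mm = 1, depth_cm = 0.2)
  m <- matrix(100L, geom$rows, geom$cols)
  fr <- frame_stream(list(m, m, m), t = c(0, 1, 5), geom)
  trk <- tibble::tibble(t = c(-0.5, 1.5), x = 0, y = 0, z = c(0, 1),
                        rx = 0, ry = 0, rz = 0)
  expect_message(pnn_reconstruct(fr, trk, pnn_config(0.1, 0)),
                 "dropped 1 frame")
})

test_that("temporal offsets are recovered within one frame interval", {
  ph <- default_phantom()
  geom <- image_geometry(width_mm = 10)
  beam <- beam_profile()
  cfg <- acquisition_config("freehand", velocity = 3, sweep_length_mm = 25)
  traj <- calibration_trajectory(cfg, geom)
  frame_interval_ms <- 1000 / geom$fps
  for (inj in c(-30, 0, 50)) {
    acq <- acquire(ph, cfg, beam, geom, trajectory = traj, seed = 4,
                   noise = tracking_noise(position_rms_mm = 0,
                                          orientation_rms_deg = 0,
                                          temporal_offset_ms = inj))
    est <- temporal_offset(acq$tracking, acq$frames)
    expect_lt(abs(est$offset_ms - inj), frame_interval_ms,
              label = sprintf("injected %d ms, estimated %.1f ms",
                              inj, est$offset_ms))
  }
  # brute-force oracle: the -30 ms case re-estimated by scanning every
  # integer-sample lag of the raw signals directly
  acq <- acquire(ph, cfg, beam, geom, trajectory = traj, seed = 4,
                 noise = tracking_noise(position_rms_mm = 0,
                                        orientation_rms_deg = 0,
                                        temporal_offset_ms = -30))
  srow <- vapply(acq$frames$frames, function(f) {
    which(f[, ceiling(ncol(f) / 2)] >= 100)[1]
  }, numeric(1))
  grid <- seq(max(min(acq$frames$t), min(acq$tracking$t)),
              min(max(acq$frames$t), max(acq$tracking$t)), by = 0.005)
  si <- approx(acq$frames$t, srow, xout = grid, rule = 2)$y
  st <- approx(acq$tracking$t, acq$tracking$z, xout = grid, rule = 2)$y
  dsi <- diff(si); dst <- diff(st)
  lagscan <- vapply(-100:100, function(k) {
    n <- length(dsi)
    if (k >= 0) cor(dsi[seq_len(n - k)], dst[seq_len(n - k) + k])
    else cor(dsi[seq_len(n + k) - k], dst[seq_len(n + k)])
  }, numeric(1))
  oracle_ms <- (-100:100)[which.max(abs(lagscan))] * 5
  expect_lt(abs(oracle_ms - (-30)), frame_interval_ms)
})

test_that("motionless streams make the temporal lag undefined", {
  geom <- small_geom(width_mm = 2, depth_cm = 1)
  m <- matrix(c(rep(0L, 40), rep(200L, geom$rows - 40)), geom$rows, geom$cols)
  fr <- frame_stream(rep(list(m), 31), t = seq(0, 3, by = 0.1), geom)
  trk <- tibble::tibble(t = seq(0, 3, by = 0.025), x = 0, y = 0, z = 0,
                        rx = 0, ry = 0, rz = 0)
  expect_error(temporal_offset(trk, fr), class = "us_undefined_lag")
})
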