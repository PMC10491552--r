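# Grid orchestration on a compact geometry; the full 13 x 3 protocol run
# lives in the acceptance suite.

grid_geom <- image_geometry(depth_cm = 4.3, pixel_spacing_axial = 0.25,
                            pixel_spacing_lateral = 0.25, width_mm = 40)

test_that("a grid subset produces one complete report row per acquisition", {
  sub <- protocol_grid()[c(1, 4, 9), ]  # freehand + stepwise + continuous
  res <- run_experiment_grid(sub, n_repeats = 2, seed = 7, geom = grid_geom,
                             sweep_length_mm = 44)
  expect_equal(nrow(res$report), 6)
  expect_equal(sum(res$report$method == "freehand"), 2)
  expect_true(all(c("experiment", "acquisition", "seed", "notes") %in%
                    names(res$report)))
  # the sweep is too short for the 50-mm elevation span: explicit absence
  expect_true(all(is.na(res$report$dist_cal_elevation_mm)))
  expect_true(all(grepl("dist_cal_elevation", res$report$notes)))
  # core metrics all present
  for (m in c("contrast_resolution", "resolution_axial_mm",
              "dist_cal_axial_mm", "stability_rms_mm")) {
    expect_true(all(is.finite(res$report[[m]])), label = m)
  }
  expect_s3_class(res$summary, "tbl_df")
})

test_that("grid runs are reproducible from (config, seed)", {
  sub <- protocol_grid()[c(3, 4), ]
  r1 <- run_experiment_grid(sub, n_repeats = 1, seed = 3, geom = grid_geom,
                            sweep_length_mm = 12)
  r2 <- run_experiment_grid(sub, n_repeats = 1, seed = 3, geom = grid_geom,
                            sweep_length_mm = 12)
  expect_identical(r1$report, r2$report)
  r3 <- run_experiment_grid(sub, n_repeats = 1, seed = 4, geom = grid_geom,
                            sweep_length_mm = 12)
  expect_false(identical(r1$report$stability_rms_mm,
                         r3$report$stability_rms_mm))
})

test_that("motorized stability degrades monotonically with injected jitter", {
  # seeded ladder of axial jitter amplitudes, measured through the full
  # stack + segment + stability chain
  geom <- small_geom(width_mm = 6)
  ph <- quiet_phantom(surface_curvature = 0)
  cfg <- acquisition_config("motorized", "stepwise", step_size_mm = 0.5,
                            sweep_length_mm = 50)
  base_traj <- motorized_trajectory(cfg, geom)
  rms_at <- function(amp) {
    vals <- vapply(1:4, function(s) {
      traj <- perturb_axial(base_traj, amp, seed = s)
      acq <- acquire(ph, cfg, beam_profile(), geom, seed = s,
                     trajectory = traj)
      vol <- stack_volume(acq$frames, 0.5)
      stability(surface_profile(vol))$rms_mm
    }, numeric(1))
    median(vals)
  }
  ladder <- vapply(c(0, 0.1, 0.25, 0.5), rms_at, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("inter-operator ICC table covers the dual-operator cells", {
  skip_if_not_installed("withr")
  # synthetic report: 3 repeats per operator in the three comparable cells
  withr::with_seed(5, {
    mk <- function(method, movement, op, mu) {
      tibble::tibble(method = method, movement = movement, step_size_mm = 0.5,
                     operator = op, contrast_resolution = rnorm(3, 6.3, 0.1),
                     resolution_axial_mm = rnorm(3, 0.33, 0.02),
                     resolution_elevation_mm = rnorm(3, 1.0, 0.05),
                     dist_cal_axial_mm = rnorm(3, mu, 0.05),
                     dist_cal_elevation_mm = rnorm(3, 2, 0.1),
                     stability_rms_mm = rnorm(3, 0.06, 0.005),
                     stability_min_mm = -0.2, stability_max_mm = 0.2,
                     notes = NA_character_, compounding = FALSE)
    }
    rep_tbl <- dplyr::bind_rows(
      mk("freehand", "freehand", "A", 2.2), mk("freehand", "freehand", "B", 2.3),
      mk("motorized", "stepwise", "A", 1.8), mk("motorized", "stepwise", "B", 1.8),
      mk("motorized", "continuous", "A", 1.7), mk("motorized", "continuous", "B", 1.7)
    )
  })
  icc_tbl <- operator_icc_table(rep_tbl)
  expect_setequal(unique(icc_tbl$movement),
                  c("freehand", "stepwise", "continuous"))
  expect_equal(nrow(icc_tbl), 18)  # 6 metrics x 3 cells
  # the ICC(2,1) point estimate is bounded above by 1; small-sample
  # estimates may dip below -1 when raters disagree systematically
  expect_true(all(icc_tbl$icc <= 1))
})
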