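test_that("contrast slope is exact for exactly linear cylinder means", {
  # volume assembled directly: five uniform blocks at gray = 120 + g*dB
  g_true <- 6.3
  levels <- c(-9, -6, -3, 3, 6)
  arr <- array(120, dim = c(20, 50, 5))
  for (i in seq_along(levels)) {
    arr[6:15, ((i - 1) * 10 + 2):((i - 1) * 10 + 9), ] <-
      120 + g_true * levels[i]
  }
  vol <- us_volume(arr, spacing = c(0.1, 0.1, 0.5))
  rois <- lapply(seq_along(levels), function(i) {
    roi_spec(c(10, (i - 1) * 10 + 5, 3), half_extent = c(3, 2, 2))
  })
  res <- contrast_resolution(vol, rois, levels)
  expect_equal(res$slope, g_true, tolerance = 1e-12)
  expect_equal(res$r_squared, 1)
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(glance(res)$slope, g_true)

  # all means equal -> slope 0
  flat <- us_volume(array(100, dim = c(20, 50, 5)),
                    spacing = c(0.1, 0.1, 0.5))
  expect_equal(contrast_resolution(flat, rois, levels)$slope, 0)
})

test_that("marker peaks honour the centre-pixel tie-break", {
  arr <- array(0, dim = c(9, 9, 9))
  arr[5, 4, 6] <- 255
  vol <- us_volume(arr, spacing = c(1, 1, 1))
  pk <- find_marker_peak(vol, roi_spec(c(5, 5, 5), c(4, 4, 4)))
  expect_equal(unname(pk), c(5, 4, 6))

  # three collinear tied voxels -> the middle one
  arr2 <- array(0, dim = c(9, 9, 9))
  arr2[4:6, 5, 5] <- 255
  vol2 <- us_volume(arr2, spacing = c(1, 1, 1))
  pk2 <- find_marker_peak(vol2, roi_spec(c(5, 5, 5), c(4, 4, 4)))
  expect_equal(unname(pk2), c(5, 5, 5))

  # flat ROI -> no-marker error
  flat <- us_volume(array(7, dim = c(9, 9, 9)), spacing = c(1, 1, 1))
  expect_error(find_marker_peak(flat, roi_spec(c(5, 5, 5), c(3, 3, 3))),
               class = "us_no_marker")
})

test_that("distance error implements |actual - measured| with mm spacing", {
  d <- distance_error(c(1, 1, 1), c(251, 1, 1), spacing = c(0.12, 0.12, 0.5),
                      d_actual = 30)
  expect_equal(d$d_measured, 30)
  expect_equal(d$error_mm, 0)

  # textbook arithmetic: |50 - 45.78| = 4.22
  d2 <- distance_error(c(1, 1, 1), c(1, 1, 101), spacing = c(1, 1, 0.4578),
                       d_actual = 50)
  expect_equal(d2$error_mm, 4.22, tolerance = 1e-12)

  # metric properties: symmetry in the two points, zero iff equal distances,
  # equivariance under a common mm rescaling of the measured distance
  p1 <- c(3, 4, 5); p2 <- c(10, 2, 8); sp <- c(0.2, 0.2, 0.3)
  e12 <- distance_error(p1, p2, sp, 12)
  e21 <- distance_error(p2, p1, sp, 12)
  expect_equal(e12$error_mm, e21$error_mm)
  ezero <- distance_error(p1, p2, sp, e12$d_measured)
  expect_equal(ezero$error_mm, 0)
  escaled <- distance_error(p1, p2, 2 * sp, 24)
  expect_equal(escaled$d_measured, 2 * e12$d_measured)
  expect_error(distance_error(p1, p1, sp, 10), class = "us_invalid_roi")
})

test_that("line profiles span the volume and reject the lateral axis", {
  vol <- gaussian_point_volume()
  pk <- find_marker_peak(vol, roi_spec(c(41, 11, 21), c(10, 5, 10)))
  pr_ax <- line_profile(vol, pk, "axial")
  expect_equal(nrow(pr_ax), dim(vol)[1])
  expect_equal(max(pr_ax$gray), max(vol$data))
  pr_el <- line_profile(vol, pk, "elevation")
  expect_equal(nrow(pr_el), dim(vol)[3])
  expect_error(line_profile(vol, pk, "lateral"), class = "us_invalid_axis")

  flat <- us_volume(array(55, dim = c(10, 10, 10)), spacing = c(1, 1, 1))
  pr <- line_profile(flat, c(5, 5, 5), "axial")
  expect_equal(unique(pr$gray), 55)
})

test_that("FWHM matches the Gaussian closed form over a sigma ladder", {
  spacing <- 0.1
  for (sig in seq(0.1, 1.0, by = 0.1)) {
    n <- max(201, ceiling(12 * sig / spacing))
    pos <- (seq_len(n) - 1) * spacing
    c0 <- pos[ceiling(n / 2)]
    prof <- tibble::tibble(position_mm = pos,
                           gray = 200 * exp(-(pos - c0)^2 / (2 * sig^2)))
    attr(prof, "axis") <- "axial"
    attr(prof, "spacing_mm") <- spacing
    class(prof) <- c("us_line_profile", class(prof))
    res <- fwhm(prof)
    expect_lt(abs(res$fwhm_mm - 2 * sqrt(2 * log(2)) * sig), spacing / 2)
    expect_lt(res$left_mm, res$peak_position_mm)
    expect_gt(res$right_mm, res$peak_position_mm)
  }
})

test_that("FWHM of a noise-free sigma = 0.2 mm Gaussian is 0.471 mm", {
  spacing <- 0.1
  pos <- seq(0, 20, by = spacing)
  prof <- tibble::tibble(position_mm = pos,
                         gray = 180 * exp(-(pos - 10)^2 / (2 * 0.2^2)))
  attr(prof, "axis") <- "axial"
  attr(prof, "spacing_mm") <- spacing
  class(prof) <- c("us_line_profile", class(prof))
  expect_equal(fwhm(prof)$fwhm_mm, 0.471, tolerance = 0.011 / 0.471)
})

test_that("FWHM of a symmetric triangle of 2 mm base is exactly 1 mm", {
  pos <- seq(0, 4, by = 0.05)
  gray <- pmax(0, 200 * (1 - abs(pos - 2)))  # base 2 mm, apex 200 at 2 mm
  prof <- tibble::tibble(position_mm = pos, gray = gray)
  attr(prof, "axis") <- "elevation"
  attr(prof, "spacing_mm") <- 0.05
  class(prof) <- c("us_line_profile", class(prof))
  expect_equal(fwhm(prof)$fwhm_mm, 1.0, tolerance = 1e-9)
})

test_that("FWHM errors on clipped peaks and flat profiles", {
  pos <- seq(0, 2, by = 0.1)
  rising <- tibble::tibble(position_mm = pos, gray = 100 * pos)
  attr(rising, "axis") <- "axial"
  class(rising) <- c("us_line_profile", class(rising))
  expect_error(fwhm(rising), class = "us_clipped_peak")

  flat <- tibble::tibble(position_mm = pos, gray = rep(9, length(pos)))
  attr(flat, "axis") <- "axial"
  class(flat) <- c("us_line_profile", class(flat))
  expect_error(fwhm(flat), class = "us_no_peak")
})

test_that("surface profiles recover flat, ramp and known curved surfaces", {
  mk_vol <- function(surface_rows, nrow = 60) {
    nz <- length(surface_rows)
    arr <- array(0, dim = c(nrow, 5, nz))
    for (k in seq_len(nz)) arr[surface_rows[k]:nrow, , k] <- 200
    us_volume(arr, spacing = c(0.1, 0.1, 0.5))
  }
  # flat surface: f constant, Df all zero
  vol <- mk_vol(rep(30, 40))
  sp <- surface_profile(vol)
  expect_equal(length(unique(sp$f_px)), 1)
  expect_true(all(attr(sp, "Df") == 0))

  # ramp of one pixel per column: Df all 1
  vol2 <- mk_vol(10 + seq_len(40))
  sp2 <- surface_profile(vol2)
  expect_true(all(attr(sp2, "Df") == 1))

  # known per-column heights are recovered exactly (sharp edge, half-gray
  # crossing adds the same 0.5 px offset to every column)
  heights <- c(20, 22, 21, 25, 24, 23, 26, 22, 20, 24, 25, 21,
               23, 22, 26, 20, 24, 21, 25, 23)
  vol3 <- mk_vol(rep(heights, each = 2))
  sp3 <- surface_profile(vol3)
  n <- ceiling(0.25 * dim(vol3)[3])
  expect_equal(nrow(sp3), n)
  truth <- rep(heights, each = 2)
  start <- floor((dim(vol3)[3] - n) / 2) + 1
  expect_equal(diff(sp3$f_px),
               diff(truth[start:(start + n - 1)]))

  # missing surface in a baseline column is an explicit error
  arr <- vol$data; arr[, , 20] <- 0
  expect_error(surface_profile(us_volume(arr, spacing = vol$spacing)),
               class = "us_no_surface")
})

test_that("integer surface localisation reproduces the strict binary procedure", {
  arr <- array(0, dim = c(30, 3, 12))
  rows <- c(10, 10, 11, 12, 12, 11, 10, 11, 12, 11, 10, 10)
  for (k in 1:12) arr[rows[k]:30, , k] <- 150
  vol <- us_volume(arr, spacing = c(0.2, 0.2, 0.5))
  sp <- surface_profile(vol, subpixel = FALSE)
  expect_true(all(sp$f_px == round(sp$f_px)))
})

test_that("stability implements the RMS of the surface derivative", {
  # all-zero derivative
  s0 <- stability(as_surface_profile(rep(5, 10), 0.1))
  expect_equal(s0$rms_mm, 0)
  expect_equal(s0$min_mm, 0)
  expect_equal(s0$max_mm, 0)

  # alternating +-1 px at 0.1 mm spacing
  s1 <- stability(as_surface_profile(c(0, 1, 0, 1, 0), 0.1))
  expect_equal(s1$rms_mm, 0.1)
  expect_equal(s1$min_mm, -0.1)
  expect_equal(s1$max_mm, 0.1)

  # linear ramp with slope s px/slice: rms = min = max = |s| * spacing
  for (slope in c(0.5, 2)) {
    sr <- stability(as_surface_profile(slope * (0:20), 0.12))
    expect_equal(sr$rms_mm, slope * 0.12)
    expect_equal(sr$min_mm, slope * 0.12)
    expect_equal(sr$max_mm, slope * 0.12)
  }
})

test_that("stability recovers injected Gaussian surface jitter", {
  # i.i.d. per-slice increments on a flat region; RMS of a Gaussian sample
  # estimates its sigma
  sigma_px <- 3
  errs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      f <- cumsum(c(20, rnorm(160, 0, sigma_px)))
      st <- stability(as_surface_profile(f, 0.1))
      st$rms_mm
    })
  }, numeric(1))
  expect_lt(abs(median(errs) - sigma_px * 0.1) / (sigma_px * 0.1), 0.15)
})

test_that("run_qa reports every metric or an explicit reason", {
  ph <- quiet_phantom()
  geom <- small_geom(width_mm = 40)
  cfg <- acquisition_config("motorized", "stepwise", step_size_mm = 0.5,
                            sweep_length_mm = 60)
  acq <- acquire(ph, cfg, beam_profile(), geom, seed = 1)
  vol <- stack_volume(acq$frames, 0.5)
  row <- run_qa(vol, ph, movement = "stepwise", step_size_mm = 0.5)
  metrics <- c("contrast_resolution", "resolution_axial_mm",
               "resolution_elevation_mm", "dist_cal_axial_mm",
               "dist_cal_elevation_mm", "stability_rms_mm")
  expect_true(all(is.finite(unlist(row[metrics]))))

  # determinism: same volume twice -> identical rows
  expect_identical(row, run_qa(vol, ph, movement = "stepwise",
                               step_size_mm = 0.5))

  # a sweep too short for the elevation filament span: metric absent with
  # a reason, everything else still reported
  cfg2 <- acquisition_config("motorized", "stepwise", step_size_mm = 0.5,
                             sweep_length_mm = 42)
  acq2 <- acquire(ph, cfg2, beam_profile(), geom, seed = 1)
  vol2 <- stack_volume(acq2$frames, 0.5)
  row2 <- run_qa(vol2, ph)
  expect_true(is.na(row2$dist_cal_elevation_mm))
  expect_match(row2$notes, "dist_cal_elevation")
  expect_true(is.finite(row2$contrast_resolution))
})
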