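# End-to-end orchestration of the acquisition-protocol experiment grid.

#' The 13-experiment protocol grid
#'
#' The standard comparison protocol: two freehand experiments (operators A
#' and B) and eleven motorized experiments covering step sizes 0.1-1.0 mm,
#' stepwise and continuous movement, one compound-imaging setting and a
#' second operator at 0.5 mm. Three acquisitions per experiment give
#' 6 freehand and 33 motorized report rows.
#'
#' @return A tibble with columns `experiment`, `operator`, `method`,
#'   `step_size_mm`, `movement`, `compounding`.
#' @export
protocol_grid <- function() {
  tibble::tribble(
    ~experiment, ~operator, ~method,      ~step_size_mm, ~movement,    ~compounding,
    1L,  "A", "freehand",  NA,  "freehand",   FALSE,
    2L,  "B", "freehand",  NA,  "freehand",   FALSE,
    3L,  "A", "motorized", 1.0, "stepwise",   FALSE,
    4L,  "A", "motorized", 0.5, "stepwise",   FALSE,
    5L,  "A", "motorized", 0.5, "stepwise",   TRUE,
    6L,  "B", "motorized", 0.5, "stepwise",   FALSE,
    7L,  "A", "motorized", 0.2, "stepwise",   FALSE,
    8L,  "A", "motorized", 0.1, "stepwise",   FALSE,
    9L,  "A", "motorized", 1.0, "continuous", FALSE,
    10L, "A", "motorized", 0.5, "continuous", FALSE,
    11L, "B", "motorized", 0.5, "continuous", FALSE,
    12L, "A", "motorized", 0.2, "continuous", FALSE,
    13L, "A", "motorized", 0.1, "continuous", FALSE
  )
}

#' Tremor parameters per simulated operator
#'
#' Operator B is modelled as the steadier hand (smaller tremor amplitude and
#' drift) — a documented modelling choice for simulating inter-operator
#' variability, not a physiological claim.
#'
#' @param operator `"A"` or `"B"`.
#' @return A [tremor_model()].
#' @export
operator_tremor <- function(operator = c("A", "B")) {
  operator <- match.arg(operator)
  if (operator == "A") {
    tremor_model(amplitude_mm = c(0.15, 0.10, 0.15), band_hz = 9,
                 walk_sd_mm = 0.04, angular_jitter_deg = 0.3)
  } else {
    tremor_model(amplitude_mm = c(0.10, 0.07, 0.10), band_hz = 10,
                 walk_sd_mm = 0.03, angular_jitter_deg = 0.2)
  }
}

#' Run the full experiment grid
#'
#' Simulates every experiment of the grid `n_repeats` times
#' (simulate, reconstruct, measure), producing one QA report row per
#' acquisition plus per-method summary statistics. Deterministic given
#' `seed`. A failure in any stage aborts that acquisition only and is
#' recorded in the report row's `notes`.
#'
#' Continuous motorized sweeps use `velocity = step_size_mm * fps`, so the
#' effective step size equals the grid's step-size column. Freehand sweeps
#' are reconstructed by pixel-nearest-neighbour gridding after temporal
#' calibration (estimated from the streams, falling back to the configured
#' tracker offset when the estimate fails); motorized sweeps are stacked.
#'
#' @param grid Experiment tibble, default [protocol_grid()].
#' @param n_repeats Acquisitions per experiment (3 in the full protocol).
#' @param seed Master seed; every acquisition derives its own sub-seed.
#' @param phantom,beam,geom Simulation ground truth and imaging settings.
#' @param sweep_length_mm Elevation travel per acquisition (mm).
#' @param pnn [pnn_config()] for freehand reconstruction.
#' @param noise [tracking_noise()] for freehand tracking.
#' @param freehand_velocity Freehand sweep speed (mm/s).
#' @param progress Print one line per acquisition.
#' @return A list of class `us_grid_result`: `report` (one row per
#'   acquisition), `summary` (per-method mean/SD per metric), and the input
#'   `grid` and `seed`.
#' @export
run_experiment_grid <- function(grid = protocol_grid(), n_repeats = 3, seed = 1,
                                phantom = default_phantom(),
                                beam = beam_profile(),
                                geom = image_geometry(),
                                sweep_length_mm = 60,
                                pnn = pnn_config(),
                                noise = tracking_noise(),
                                freehand_velocity = 2,
                                progress = FALSE) {
  n_total <- nrow(grid) * n_repeats
  seeds <- derive_seeds(seed, n_total)
  rows <- vector("list", n_total)
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    ex <- grid[g, ]
    for (rep_i in seq_len(n_repeats)) {
      idx <- idx + 1L
      sub_seed <- seeds[idx]
      if (progress) {
        message(sprintf("experiment %d (%s %s), acquisition %d",
                        ex$experiment, ex$method, ex$movement, rep_i))
      }
      rows[[idx]] <- tryCatch({
        row <- run_grid_acquisition(ex, phantom, beam, geom, sweep_length_mm,
                                    pnn, noise, freehand_velocity, sub_seed)
        row$compounding <- ex$compounding
        row$experiment <- ex$experiment
        row$acquisition <- rep_i
        row$seed <- sub_seed
        row
      }, error = function(e) {
        tibble::tibble(method = ex$method, movement = ex$movement,
                       step_size_mm = ex$step_size_mm, operator = ex$operator,
                       contrast_resolution = NA_real_,
                       resolution_axial_mm = NA_real_,
                       resolution_elevation_mm = NA_real_,
                       dist_cal_axial_mm = NA_real_,
                       dist_cal_elevation_mm = NA_real_,
                       stability_rms_mm = NA_real_, stability_min_mm = NA_real_,
                       stability_max_mm = NA_real_,
                       notes = paste("acquisition failed:", conditionMessage(e)),
                       experiment = ex$experiment, acquisition = rep_i,
                       seed = sub_seed)
      })
    }
  }
  report <- dplyr::bind_rows(rows)
  structure(list(report = report,
                 summary = summarize_metrics(qa_long(report), .data$method),
                 grid = grid, seed = seed),
            class = "us_grid_result")
}

run_grid_acquisition <- function(ex, phantom, beam, geom, sweep_length_mm,
                                 pnn, noise, freehand_velocity, sub_seed) {
  if (ex$method == "motorized") {
    cfg <- if (ex$movement == "stepwise") {
      acquisition_config("motorized", "stepwise", step_size_mm = ex$step_size_mm,
                         compounding = ex$compounding,
                         sweep_length_mm = sweep_length_mm)
    } else {
      acquisition_config("motorized", "continuous",
                         velocity = ex$step_size_mm * geom$fps,
                         sweep_length_mm = sweep_length_mm)
    }
    acq <- acquire(phantom, cfg, beam, geom, seed = sub_seed)
    vol <- stack_volume(acq$frames, ex$step_size_mm)
  } else {
    cfg <- acquisition_config("freehand", velocity = freehand_velocity,
                              sweep_length_mm = sweep_length_mm)
    acq <- acquire(phantom, cfg, beam, geom,
                   tremor = operator_tremor(ex$operator), noise = noise,
                   seed = sub_seed)
    off <- tryCatch(temporal_offset(acq$tracking, acq$frames)$offset_ms,
                    error = function(e) noise$temporal_offset_ms)
    trk <- apply_temporal_offset(acq$tracking, off)
    vol <- pnn_reconstruct(acq$frames, trk, pnn)
  }
  run_qa(vol, phantom, method = ex$method, movement = ex$movement,
         step_size_mm = ex$step_size_mm, operator = ex$operator)
}

#' @export
print.us_grid_result <- function(x, ...) {
  cat(sprintf("<us_grid_result> %d acquisitions over %d experiments (seed %d)\n",
              nrow(x$report), nrow(x$grid), x$seed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Inter-operator ICC table
#'
#' For every metric and every (method, movement) cell acquired by both
#' operators, computes the two-way absolute-agreement ICC between the
#' operators' repeated acquisitions (step size 0.5 mm cells in the standard
#' grid).
#'
#' @param report QA report tibble from [run_experiment_grid()].
#' @param step_size_mm Motorized step size shared by both operators.
#' @return Tibble with one row per metric x cell: operator means/SDs and the
#'   ICC with its p-value.
#' @export
operator_icc_table <- function(report, step_size_mm = 0.5) {
  long <- qa_long(report) |>
    dplyr::filter(.data$metric %in% c("contrast_resolution",
                                      "resolution_axial_mm",
                                      "resolution_elevation_mm",
                                      "dist_cal_axial_mm",
                                      "dist_cal_elevation_mm",
                                      "stability_rms_mm"))
  if (!"compounding" %in% names(long)) long$compounding <- FALSE
  cells <- long |>
    dplyr::filter(.data$method == "freehand" |
                    (!is.na(.data$step_size_mm) &
                       .data$step_size_mm == !!step_size_mm &
                       !.data$compounding)) |>
    dplyr::distinct(.data$method, .data$movement)
  out <- list()
  for (c_i in seq_len(nrow(cells))) {
    cell <- long |>
      dplyr::filter(.data$method == cells$method[c_i],
                    .data$movement == cells$movement[c_i],
                    .data$method == "freehand" |
                      .data$step_size_mm == !!step_size_mm)
    for (m in unique(cell$metric)) {
      sub <- cell |>
        dplyr::filter(.data$metric == m, is.finite(.data$value)) |>
        dplyr::group_by(.data$operator) |>
        dplyr::mutate(rep = dplyr::row_number()) |>
        dplyr::ungroup()
      wide <- tidyr::pivot_wider(sub[c("operator", "rep", "value")],
                                 names_from = "operator",
                                 values_from = "value")
      ops <- setdiff(names(wide), "rep")
      if (length(ops) < 2 || nrow(wide) < 3 || anyNA(wide[ops])) next
      icc_res <- icc_agreement(as.matrix(wide[ops]))
      stats_by <- sub |>
        dplyr::group_by(.data$operator) |>
        dplyr::summarize(mean = mean(.data$value), sd = stats::sd(.data$value),
                         .groups = "drop")
      out[[length(out) + 1]] <- tibble::tibble(
        metric = m, method = cells$method[c_i], movement = cells$movement[c_i],
        mean_A = stats_by$mean[stats_by$operator == "A"],
        sd_A = stats_by$sd[stats_by$operator == "A"],
        mean_B = stats_by$mean[stats_by$operator == "B"],
        sd_B = stats_by$sd[stats_by$operator == "B"],
        icc = icc_res$icc, p_value = icc_res$p_value
      )
    }
  }
  dplyr::bind_rows(out)
}
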