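# Aggregation and agreement statistics over repeated acquisitions.

#' Pivot a QA report to long format
#'
#' @param report A tibble of [run_qa()] rows.
#' @return Long tibble with one row per (acquisition, metric): the metadata
#'   columns plus `metric` and `value`.
#' @export
qa_long <- function(report) {
  metric_cols <- c("contrast_resolution", "resolution_axial_mm",
                   "resolution_elevation_mm", "dist_cal_axial_mm",
                   "dist_cal_elevation_mm", "stability_rms_mm",
                   "stability_min_mm", "stability_max_mm")
  tidyr::pivot_longer(report, cols = dplyr::any_of(metric_cols),
                      names_to = "metric", values_to = "value")
}

#' Summary table of metrics per group
#'
#' Mean and standard deviation of each metric per grouping cell —
#' the per-method summary of a freehand-versus-motorized comparison (all
#' motorized acquisitions pooled against all freehand acquisitions), or any
#' finer cell.
#'
#' @param table Long metric tibble (see [qa_long()]): needs `metric`,
#'   `value` and the grouping columns.
#' @param ... Grouping columns (tidy-select), default `method`.
#' @return Tibble with `mean`, `sd` and `n` per metric and group.
#' @export
summarize_metrics <- function(table, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) groups <- rlang::quos(.data$method)
  table |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$metric, !!!groups) |>
    dplyr::summarize(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
}

#' Paired-samples t-test
#'
#' Classical paired t-test between two matched series of metric values, e.g.
#' stepwise versus continuous movement of the same settings, or with versus
#' without compound imaging. All-zero differences have no defined t
#' statistic and raise an error.
#'
#' @param x,y Matched numeric vectors (equal length, at least 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_diff`,
#'   `conf_low`, `conf_high`, `method`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_us("paired t-test needs two matched vectors of equal length >= 2",
            "us_invalid_pairs")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    stop_us("all paired differences are identical: the t statistic is undefined (zero variance)",
            "us_zero_variance")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, mean_diff = unname(tt$estimate),
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                 method = "paired t-test")
}

#' Welch two-sample t-test between methods
#'
#' Unpaired Welch approximation for comparing freehand against motorized
#' values of one metric (the full study design would fit a linear mixed
#' model on the long table; this package emits that table and reports
#' Welch's t as a built-in approximation).
#'
#' @param x,y Numeric vectors (unequal length allowed).
#' @return One-row tibble as in [paired_ttest()].
#' @export
welch_ttest <- function(x, y) {
  tt <- stats::t.test(x, y)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 mean_diff = unname(tt$estimate[1] - tt$estimate[2]),
                 conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
                 method = "Welch two-sample t-test")
}

#' Inter-operator agreement: ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation computed from the ANOVA mean squares: with `n` targets
#' (acquisitions) and `k` raters (operators),
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the between-target, between-rater and residual
#' mean squares. The p-value is the F-test `MSR / MSE` on
#' `(n-1, (n-1)(k-1))` degrees of freedom. Zero between-target variance
#' yields an ICC of 0 with a warning rather than an error.
#'
#' @param ratings Numeric matrix, targets (acquisitions) in rows and raters
#'   (operators) in columns; at least 3 x 2.
#' @return One-row tibble: `icc`, `p_value`, `model`, `n_targets`,
#'   `n_raters`, `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) {
    stop_us("ICC needs at least 3 targets and 2 raters", "us_invalid_ratings")
  }
  gm <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(denom) || denom <= 0) {
    warn("zero between-target variance: ICC is not identifiable, reporting 0")
    icc <- 0
  } else {
    icc <- (msr - mse) / denom
  }
  p <- if (mse > 0) {
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    NA_real_
  }
  tibble::tibble(icc = icc, p_value = p,
                 model = "ICC(2,1) two-way random, absolute agreement",
                 n_targets = n, n_raters = k, msr = msr, msc = msc, mse = mse)
}
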