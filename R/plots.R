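# ggplot2 visualisations

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline geom_smooth geom_raster labs theme_minimal scale_fill_gradient
#' @export
ggplot2::autoplot

#' Plot a line profile with its FWHM measurement
#'
#' @param object A [line_profile()].
#' @param fwhm Optional [fwhm()] result to overlay (half level and
#'   crossings).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.us_line_profile <- function(object, fwhm = NULL, ...) {
  p <- ggplot(object, aes(x = .data$position_mm, y = .data$gray)) +
    geom_line(color = "grey30") +
    labs(x = sprintf("%s position (mm)", attr(object, "axis")),
         y = "gray value") +
    theme_minimal()
  if (!is.null(fwhm)) {
    p <- p +
      geom_hline(yintercept = fwhm$half_level, linetype = "dashed",
                 color = "red") +
      geom_vline(xintercept = c(fwhm$left_mm, fwhm$right_mm),
                 linetype = "dotted", color = "red")
  }
  p
}

#' Plot the contrast-resolution regression
#'
#' Mean cylinder gray versus nominal echo level with the fitted line whose
#' slope is the contrast resolution.
#'
#' @param object A [contrast_resolution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.us_contrast <- function(object, ...) {
  ggplot(object$data, aes(x = .data$level_db, y = .data$mean_gray)) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linetype = "dashed", color = "grey50") +
    geom_point(size = 2) +
    labs(x = "nominal level (dB)", y = "mean gray value",
         subtitle = sprintf("slope %.2f gray/dB, r² = %.3f",
                            object$slope, object$r_squared)) +
    theme_minimal()
}

#' Plot the segmented surface profile
#'
#' Baseline-to-surface distance per elevation column of the mid-lateral
#' plane; slice-to-slice jumps are the tremor signature the stability
#' statistic summarises.
#'
#' @param object A [surface_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.us_surface_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$column, y = .data$f_px)) +
    geom_line() +
    geom_point(size = 0.6) +
    labs(x = "elevation column", y = "distance to surface (px)") +
    theme_minimal()
}

#' Mid-volume slice image
#'
#' Raster view of the mid-lateral (axial x elevation) plane, depth downward.
#'
#' @param object An `us_volume`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.us_volume <- function(object, ...) {
  d <- dim(object$data)
  plane <- object$data[, ceiling(d[2] / 2), ]
  df <- tibble::as_tibble(expand.grid(i = seq_len(d[1]), k = seq_len(d[3])))
  df$gray <- as.vector(plane)
  ggplot(df, aes(x = .data$k, y = .data$i, fill = .data$gray)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    labs(x = "elevation slice", y = "axial row", fill = "gray") +
    theme_minimal()
}
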