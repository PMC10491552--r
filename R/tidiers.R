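# broom-style tidiers for the result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname us3dqa-tidiers
#' @param x A result object.
#' @param ... Unused.
#' @export
tidy.us_contrast <- function(x, ...) {
  out <- tibble::as_tibble(summary(x$fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out
}

#' Tidiers for quality-metric results
#'
#' `tidy()` returns per-component estimates (regression terms, crossing
#' positions, per-column surface heights); `glance()` returns the one-row
#' metric summary.
#'
#' @name us3dqa-tidiers
NULL

#' @rdname us3dqa-tidiers
#' @export
glance.us_contrast <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared)
}

#' @rdname us3dqa-tidiers
#' @export
tidy.us_fwhm <- function(x, ...) {
  tibble::tibble(axis = x$axis %||% NA_character_, fwhm_mm = x$fwhm_mm,
                 peak_gray = x$peak_gray, half_level = x$half_level,
                 left_mm = x$left_mm, right_mm = x$right_mm,
                 peak_position_mm = x$peak_position_mm)
}

#' @rdname us3dqa-tidiers
#' @export
glance.us_fwhm <- function(x, ...) tibble::tibble(fwhm_mm = x$fwhm_mm)

#' @rdname us3dqa-tidiers
#' @export
tidy.us_surface_profile <- function(x, ...) {
  tibble::tibble(column = x$column, f_px = x$f_px,
                 Df_px = c(attr(x, "Df"), NA_real_))
}

#' @rdname us3dqa-tidiers
#' @export
glance.us_surface_profile <- function(x, ...) {
  s <- stability(x)
  tibble::as_tibble(s)
}
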