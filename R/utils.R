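#' @importFrom rlang abort warn .data %||%
#' @importFrom stats median approx coef lm pf sd setNames
#' @importFrom utils head tail
#' @import tibble
NULL

# Gaussian FWHM <-> sigma conversion constant, 2*sqrt(2*log(2))
FWHM_K <- 2 * sqrt(2 * log(2))

#' Convert a Gaussian full width at half maximum to its standard deviation
#'
#' Resolution in ultrasound quality assurance is quoted as the -6 dB full
#' width at half maximum (FWHM) of a point-target profile. For a Gaussian
#' point-spread function FWHM = 2 * sqrt(2 * log(2)) * sigma.
#'
#' @param fwhm Full width at half maximum (mm).
#' @return Standard deviation sigma in the same units.
#' @export
#' @examples
#' fwhm_to_sigma(1.02)
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_K

#' @rdname fwhm_to_sigma
#' @param sigma Gaussian standard deviation (mm).
#' @export
sigma_to_fwhm <- function(sigma) sigma * FWHM_K

# run code under a fixed seed without disturbing the caller's RNG;
# seed = NULL leaves the RNG stream alone.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# draw n sub-seeds (< 2^31) deterministically from one master seed
derive_seeds <- function(seed, n) {
  with_seed_maybe(seed, sample.int(.Machine$integer.max, n))
}

stop_us <- function(msg, class) {
  rlang::abort(msg, class = c(class, "us3dqa_error"))
}
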