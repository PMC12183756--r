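#' Frequency step of an acquisition
#'
#' The frequency resolution of a Fourier-transformed spectrum is the spectral
#' width divided by the number of (complex time-domain) points.
#'
#' @param spectral_width Spectral width (Hz, > 0).
#' @param n_points Number of points (integer >= 2).
#' @return Frequency step in Hz.
#' @examples
#' compute_frequency_step(11160.71, 32768) # ~0.34 Hz
#' @export
compute_frequency_step <- function(spectral_width, n_points) {
  if (!is.numeric(spectral_width) || length(spectral_width) != 1L ||
      !is.finite(spectral_width) || spectral_width <= 0) {
    stop("`spectral_width` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_points) || length(n_points) != 1L ||
      !is.finite(n_points) || n_points < 2) {
    stop("`n_points` must be a single number >= 2", call. = FALSE)
  }
  spectral_width / n_points
}

#' Check frequency-step compatibility constraints
#'
#' A distorted peak's width is roughly the natural FWHM plus the response
#' width `W`. For the correction network to resolve both ends of the scale,
#' the narrowest undistorted singlet must span more than one point
#' (`fwhm_min > delta_f`) and the broadest distorted peak must stay below 100
#' points (`W + fwhm_max < 100 * delta_f`). Failures are reported, not raised.
#'
#' @param delta_f Frequency step (Hz, > 0).
#' @param W Maximum expected response-function width (Hz, > 0).
#' @param fwhm_min,fwhm_max Narrowest/broadest expected undistorted peak FWHM
#'   (Hz, > 0).
#' @return A data.frame with one row per constraint: `constraint`, `pass`,
#'   `margin` (Hz; positive means satisfied with that much room).
#' @examples
#' validate_plan(0.34, 21, 0.4, 4)
#' @export
validate_plan <- function(delta_f, W, fwhm_min, fwhm_max) {
  args <- c(delta_f = delta_f, W = W, fwhm_min = fwhm_min, fwhm_max = fwhm_max)
  if (!all(is.finite(args)) || any(args <= 0)) {
    stop("all arguments must be positive finite numbers", call. = FALSE)
  }
  if (fwhm_min > fwhm_max) {
    stop("`fwhm_min` must not exceed `fwhm_max`", call. = FALSE)
  }
  data.frame(
    constraint = c("fwhm_min > delta_f", "W + fwhm_max < 100 * delta_f"),
    pass = c(fwhm_min > delta_f, W + fwhm_max < 100 * delta_f),
    margin = c(fwhm_min - delta_f, 100 * delta_f - (W + fwhm_max)),
    stringsAsFactors = FALSE
  )
}

#' Response-function length in points
#'
#' Returns the smallest odd integer `N` with `N * delta_f >= W`, so the
#' response kernel window covers the broadest expected response. An explicit
#' odd `n_override` may be supplied to reproduce an externally chosen length.
#'
#' @param W Maximum response width (Hz, > 0).
#' @param delta_f Frequency step (Hz, > 0).
#' @param n_override Optional odd integer >= 1 used verbatim instead of the
#'   formula.
#' @return Odd integer `N`.
#' @examples
#' response_length(21, 0.3406)  # 63
#' @export
response_length <- function(W, delta_f, n_override = NULL) {
  if (!is.null(n_override)) {
    n_override <- as.integer(n_override)
    if (length(n_override) != 1L || is.na(n_override) || n_override < 1L ||
        n_override %% 2L == 0L) {
      stop("`n_override` must be a single odd integer >= 1", call. = FALSE)
    }
    return(n_override)
  }
  if (!is.numeric(W) || length(W) != 1L || !is.finite(W) || W <= 0) {
    stop("`W` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(delta_f) || length(delta_f) != 1L || !is.finite(delta_f) ||
      delta_f <= 0) {
    stop("`delta_f` must be a single positive number", call. = FALSE)
  }
  n <- as.integer(ceiling(W / delta_f - 1e-12))
  if (n < 1L) n <- 1L
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Assemble and validate a resolution plan
#'
#' Bundles the frequency step, the response window, and the expected peak
#' widths, derives the response length `N`, and enforces the two
#' compatibility constraints of [validate_plan()].
#'
#' @inheritParams validate_plan
#' @inheritParams response_length
#' @return An object of class `resolution_plan` with fields `delta_f`, `W`,
#'   `fwhm_min`, `fwhm_max`, `n_response`.
#' @examples
#' resolution_plan(0.3406, 21, 0.4, 4)
#' @export
resolution_plan <- function(delta_f, W, fwhm_min, fwhm_max,
                            n_override = NULL) {
  rep_ <- validate_plan(delta_f, W, fwhm_min, fwhm_max)
  if (!all(rep_$pass)) {
    bad <- rep_$constraint[!rep_$pass]
    stop(sprintf("resolution plan violates: %s", paste(bad, collapse = "; ")),
         call. = FALSE)
  }
  n <- response_length(W, delta_f, n_override = n_override)
  structure(
    list(delta_f = delta_f, W = W, fwhm_min = fwhm_min,
         fwhm_max = fwhm_max, n_response = n),
    class = "resolution_plan"
  )
}

#' @export
print.resolution_plan <- function(x, ...) {
  cat(sprintf(
    "<resolution_plan> delta_f=%.4g Hz, W=%.4g Hz, FWHM %.3g..%.3g Hz, N=%d\n",
    x$delta_f, x$W, x$fwhm_min, x$fwhm_max, x$n_response))
  invisible(x)
}
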