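#' Construct a 1D frequency-domain spectrum
#'
#' A `spectrum1d` is a real-valued spectrum sampled on a uniform frequency
#' grid: point `k` (1-based) sits at `freq_start + (k - 1) * freq_step` Hz.
#' This is the container exchanged by every stage of the package, from the
#' calibration simulator to the correction pipeline.
#'
#' @param freq_start Frequency of the first point (Hz).
#' @param freq_step Frequency increment per point (Hz, > 0).
#' @param values Numeric vector of intensities (arbitrary units), length >= 2.
#' @param meta Named list of free-form annotations (e.g. spectrometer
#'   frequency in MHz). Values are coerced to character on write.
#' @return An object of class `spectrum1d`.
#' @examples
#' s <- spectrum1d(0, 0.5, c(1, 2, 1))
#' freq_axis(s)
#' @export
spectrum1d <- function(freq_start, freq_step, values, meta = list()) {
  freq_start <- as.numeric(freq_start)
  freq_step <- as.numeric(freq_step)
  values <- as.numeric(values)
  if (length(freq_start) != 1L || !is.finite(freq_start)) {
    stop("`freq_start` must be a single finite number", call. = FALSE)
  }
  if (length(freq_step) != 1L || !is.finite(freq_step) || freq_step <= 0) {
    stop("`freq_step` must be a single finite positive number", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("`values` must contain at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  structure(
    list(freq_start = freq_start, freq_step = freq_step,
         values = values, meta = meta),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf(
    "<spectrum1d> %d points, %.6g Hz .. %.6g Hz (step %.6g Hz), max %.6g\n",
    length(x$values), x$freq_start,
    x$freq_start + (length(x$values) - 1L) * x$freq_step,
    x$freq_step, max(x$values)))
  invisible(x)
}

#' Frequency axis of a spectrum
#'
#' @param spectrum A [spectrum1d].
#' @return Numeric vector of frequencies (Hz), one per point.
#' @export
freq_axis <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  spectrum$freq_start + (seq_along(spectrum$values) - 1L) * spectrum$freq_step
}

## Relative tolerance for declaring a file's frequency axis uniform.
.axis_rel_tol <- 1e-6

#' Read a spectrum from two-column ASCII text
#'
#' The dialect is: optional `# key: value` header lines, then rows of two
#' whitespace-separated numbers (frequency, intensity). Both ascending and
#' descending axes are accepted and normalized to ascending order. If the
#' header declares `unit: ppm`, a `spectrometer_frequency_MHz` header key is
#' required to convert the axis to Hz; the file is rejected otherwise.
#'
#' @param path Path to the text file.
#' @return A [spectrum1d] with `freq_step` inferred from the axis and header
#'   keys stored in `$meta`.
#' @seealso [write_spectrum_text()]
#' @export
read_spectrum_text <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("spectrum file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  freqs <- numeric(0)
  vals <- numeric(0)
  data_rows <- 0L
  freq_buf <- vector("list", length(lines))
  val_buf <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      m <- regmatches(body, regexec("^([^:]+):(.*)$", body))[[1]]
      if (length(m) == 3L) {
        meta[[trimws(m[2])]] <- trimws(m[3])
      }
      next
    }
    fields <- strsplit(ln, "[ \t]+")[[1]]
    nums <- suppressWarnings(as.numeric(fields))
    if (length(nums) != 2L || anyNA(nums)) {
      stop(sprintf("malformed line %d in '%s': '%s'", i, path, lines[[i]]),
           call. = FALSE)
    }
    data_rows <- data_rows + 1L
    freq_buf[[data_rows]] <- nums[1]
    val_buf[[data_rows]] <- nums[2]
  }
  if (data_rows < 2L) {
    stop(sprintf("spectrum file '%s' has %d data rows; need at least 2",
                 path, data_rows), call. = FALSE)
  }
  freqs <- unlist(freq_buf[seq_len(data_rows)])
  vals <- unlist(val_buf[seq_len(data_rows)])

  unit <- meta[["unit"]]
  if (!is.null(unit) && tolower(unit) == "ppm") {
    mhz <- meta[["spectrometer_frequency_MHz"]]
    if (is.null(mhz)) {
      stop("axis is in ppm but header lacks 'spectrometer_frequency_MHz'",
           call. = FALSE)
    }
    freqs <- freqs * as.numeric(mhz)
    meta[["unit"]] <- "Hz"
  }

  if (freqs[1] > freqs[data_rows]) {
    freqs <- rev(freqs)
    vals <- rev(vals)
  }
  steps <- diff(freqs)
  if (any(steps <= 0)) {
    stop(sprintf("frequency axis in '%s' is not strictly monotone", path),
         call. = FALSE)
  }
  step <- (freqs[data_rows] - freqs[1]) / (data_rows - 1L)
  if (max(abs(steps - step)) > .axis_rel_tol * step) {
    stop(sprintf(
      "frequency axis in '%s' is not uniform (max step deviation %.3g of %.6g Hz)",
      path, max(abs(steps - step)), step), call. = FALSE)
  }
  spectrum1d(freqs[1], step, vals, meta = meta)
}

#' Write a spectrum to two-column ASCII text
#'
#' Writes `# key: value` header lines for every metadata entry, then
#' full-double-precision (frequency, intensity) rows. [read_spectrum_text()]
#' inverts the file up to float formatting (<= 1e-9 relative).
#'
#' @param spectrum A [spectrum1d].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_text <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  header <- character(0)
  if (length(spectrum$meta)) {
    header <- sprintf("# %s: %s", names(spectrum$meta),
                      vapply(spectrum$meta, function(v)
                        paste(format(v, digits = 17), collapse = " "),
                        character(1)))
  }
  rows <- sprintf("%.17g %.17g", freq_axis(spectrum), spectrum$values)
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write spectrum to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

## Natural cubic spline interpolant with flat (clamped) extrapolation.
.spline_clamped <- function(x, y) {
  f <- stats::splinefun(x, y, method = "natural")
  lo <- x[1]; hi <- x[length(x)]
  ylo <- y[1]; yhi <- y[length(y)]
  function(xq) {
    out <- f(xq)
    out[xq < lo] <- ylo
    out[xq > hi] <- yhi
    out
  }
}

#' Resample a spectrum to a target frequency step
#'
#' Interpolates with a natural cubic spline onto a uniform grid of step
#' `target_step` starting at the original first point and clipped inward at
#' the far end, so no extrapolation occurs. Resampling to the spectrum's own
#' step returns the input values unchanged.
#'
#' @param spectrum A [spectrum1d].
#' @param target_step Target frequency step (Hz, > 0).
#' @return A [spectrum1d] on the new grid.
#' @export
resample <- function(spectrum, target_step) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  target_step <- as.numeric(target_step)
  if (length(target_step) != 1L || !is.finite(target_step) || target_step <= 0) {
    stop("`target_step` must be a single positive number", call. = FALSE)
  }
  span <- (length(spectrum$values) - 1L) * spectrum$freq_step
  if (span < 2 * target_step) {
    stop(sprintf(
      "spectrum span %.6g Hz is smaller than 2 * target_step = %.6g Hz",
      span, 2 * target_step), call. = FALSE)
  }
  if (abs(target_step - spectrum$freq_step) <= 1e-12 * spectrum$freq_step) {
    return(spectrum)
  }
  n_new <- floor(span / target_step) + 1L
  new_freqs <- spectrum$freq_start + (seq_len(n_new) - 1L) * target_step
  f <- .spline_clamped(freq_axis(spectrum), spectrum$values)
  spectrum1d(spectrum$freq_start, target_step, f(new_freqs),
             meta = spectrum$meta)
}

#' Interpolate a spectrum onto an explicit frequency grid
#'
#' Used by the correction pipeline to return results on the caller's original
#' grid. Same interpolation rule as [resample()]; queries outside the span are
#' clamped to the edge values.
#'
#' @param spectrum A [spectrum1d].
#' @param freq_start,freq_step,n Target grid definition.
#' @return A [spectrum1d] on the requested grid.
#' @export
resample_to_grid <- function(spectrum, freq_start, freq_step, n) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  f <- .spline_clamped(freq_axis(spectrum), spectrum$values)
  new_freqs <- freq_start + (seq_len(n) - 1L) * freq_step
  spectrum1d(freq_start, freq_step, f(new_freqs), meta = spectrum$meta)
}

#' Scale a spectrum so the tallest point hits a target height
#'
#' All points are multiplied by the same factor so the maximum equals
#' `target_height` (default 16, the height the correction network is trained
#' around). The factor is returned so the scaling can be undone with
#' [denormalize_height()].
#'
#' @param spectrum A [spectrum1d] whose maximum value is positive.
#' @param target_height Positive target for the tallest point (default 16).
#' @return A list with elements `spectrum` (scaled [spectrum1d]) and
#'   `scale_factor` (the multiplier applied).
#' @export
normalize_height <- function(spectrum, target_height = 16) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (!is.numeric(target_height) || length(target_height) != 1L ||
      !is.finite(target_height) || target_height <= 0) {
    stop("`target_height` must be a single positive number", call. = FALSE)
  }
  mx <- max(spectrum$values)
  if (mx <= 0) {
    stop("spectrum has no positive peak; cannot normalize height",
         call. = FALSE)
  }
  scale_factor <- target_height / mx
  out <- spectrum
  out$values <- spectrum$values * scale_factor
  list(spectrum = out, scale_factor = scale_factor)
}

#' Undo a peak-height normalization
#'
#' @param spectrum A [spectrum1d] previously scaled by [normalize_height()].
#' @param scale_factor The factor returned by [normalize_height()] (> 0).
#' @return The rescaled [spectrum1d].
#' @export
denormalize_height <- function(spectrum, scale_factor) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0) {
    stop("`scale_factor` must be a single positive number", call. = FALSE)
  }
  out <- spectrum
  out$values <- spectrum$values / scale_factor
  out
}
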