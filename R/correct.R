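#' Correct a distorted spectrum
#'
#' The end-user path: the input spectrum is resampled to the frequency step
#' the model was trained at, its tallest peak is scaled to the training
#' height (16), the network is run, and the output is scaled and resampled
#' back so the result lives on exactly the input grid. The tallest-peak
#' height of the input is preserved within resampling tolerance (~2%). The
#' whole pipeline is deterministic.
#'
#' A warning is issued when the input's peak-height dynamic range exceeds
#' 1:220, the range the training data covers for 90% of spectra; dominant
#' solvent peaks should be removed beforehand rather than relying on the
#' model to extrapolate.
#'
#' @param spectrum A [spectrum1d] with a positive maximum.
#' @param state A trained [shim_model] whose `meta$delta_f` is set.
#' @return An object of class `correction_result` with fields `corrected`
#'   (a [spectrum1d] on the input grid), `response_estimate`
#'   (a [response_function]), `attention` (per-point weights on the input
#'   grid, non-negative), and `scale_factor`.
#' @export
correct <- function(spectrum, state) {
  stopifnot(inherits(spectrum, "spectrum1d"), inherits(state, "shim_model"))
  if (is.na(state$meta$delta_f)) {
    stop("model carries no training delta_f; train it or set `state$meta$delta_f`",
         call. = FALSE)
  }
  if (max(spectrum$values) <= 0) {
    stop("spectrum has no positive peak; cannot normalize for correction",
         call. = FALSE)
  }
  .warn_dynamic_range(spectrum)

  work <- resample(spectrum, state$meta$delta_f)
  if (length(work$values) < 64L) {
    stop(sprintf(
      paste0("resampled spectrum has %d points (< 64); the span is too small",
             " for the model's receptive field - acquire or zero-fill a wider",
             " spectrum"),
      length(work$values)), call. = FALSE)
  }
  nh <- normalize_height(work, state$meta$target_height)
  out <- model_forward(nh$spectrum$values, state)
  # Scale back so the corrected spectrum regains the original height of the
  # tallest peak: deconvolution legitimately sharpens peaks, so the output
  # maximum (not the input scale factor alone) anchors the rescaling.
  out_max <- max(out$s_out)
  restore <- if (out_max > 0) {
    state$meta$target_height / (out_max * nh$scale_factor)
  } else {
    1 / nh$scale_factor
  }
  corrected_model_grid <- spectrum1d(work$freq_start, work$freq_step,
                                     out$s_out * restore)
  corrected <- resample_to_grid(corrected_model_grid, spectrum$freq_start,
                                spectrum$freq_step,
                                length(spectrum$values))
  corrected$meta <- spectrum$meta

  weights_spec <- spectrum1d(work$freq_start, work$freq_step,
                             pmax(out$weights, 0))
  attention <- resample_to_grid(weights_spec, spectrum$freq_start,
                                spectrum$freq_step,
                                length(spectrum$values))$values
  attention <- pmax(attention, 0)

  structure(
    list(
      corrected = corrected,
      response_estimate = response_function(out$r_out, state$meta$delta_f,
                                            endpoint_tolerance = Inf),
      attention = attention,
      scale_factor = nh$scale_factor,
      model_delta_f = state$meta$delta_f
    ),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result> %d points; scale factor %.4g; response estimate of %d points\n",
    length(x$corrected$values), x$scale_factor,
    length(x$response_estimate$values)))
  invisible(x)
}

## Heuristic dynamic-range check: tallest peak vs the smallest resolved local
## maximum that stands clear of the noise floor.
.warn_dynamic_range <- function(spectrum) {
  v <- spectrum$values
  n <- length(v)
  if (n < 16L) return(invisible(NULL))
  interior <- v[c(-1, -n)]
  is_max <- interior > v[1:(n - 2L)] & interior >= v[3:n]
  noise <- stats::mad(diff(v)) / sqrt(2)
  peaks <- interior[is_max & interior > 10 * max(noise, .Machine$double.eps)]
  if (length(peaks) >= 2L && max(peaks) / min(peaks) > 220) {
    warning(sprintf(
      paste0("peak-height dynamic range ~1:%.0f exceeds the 1:220 training",
             " coverage; consider removing dominant solvent peaks before",
             " correction"),
      max(peaks) / min(peaks)), call. = FALSE)
  }
  invisible(NULL)
}

#' Correct a batch of spectrum files
#'
#' Reads each input file, corrects it, and writes the corrected spectrum into
#' `out_dir` under the same base name. Failures are isolated per file and
#' reported in the summary; the call errors only if every file fails.
#'
#' @param paths Character vector of spectrum text files.
#' @param state A trained [shim_model].
#' @param out_dir Output directory (created if missing).
#' @return A data.frame with one row per input: `file`, `ok`, `scale_factor`,
#'   `residual_rms` (root-mean-square difference between input and corrected,
#'   relative to the peak height) and `error` message.
#' @export
batch_correct <- function(paths, state, out_dir) {
  stopifnot(inherits(state, "shim_model"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(paths) == 0L) {
    return(data.frame(file = character(0), ok = logical(0),
                      scale_factor = numeric(0), residual_rms = numeric(0),
                      error = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      sp <- read_spectrum_text(p)
      cr <- correct(sp, state)
      write_spectrum_text(cr$corrected, file.path(out_dir, basename(p)))
      data.frame(
        file = p, ok = TRUE, scale_factor = cr$scale_factor,
        residual_rms = sqrt(mean((cr$corrected$values - sp$values)^2)) /
          max(sp$values),
        error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(file = p, ok = FALSE, scale_factor = NA_real_,
                 residual_rms = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!any(report$ok)) {
    stop(sprintf("all %d corrections failed; first error: %s",
                 nrow(report), report$error[1]), call. = FALSE)
  }
  report
}

#' Summarize attention weights over frequency regions
#'
#' Sums the correction's attention weights inside each user-supplied
#' frequency interval and expresses the sums as percentages of the total
#' weight. Percentages over disjoint intervals covering the whole spectrum
#' sum to 100.
#'
#' @param result A [correction_result].
#' @param regions A two-column matrix or data.frame of interval bounds (Hz),
#'   or a list of length-2 numeric vectors; intervals must lie within the
#'   spectrum span.
#' @return A data.frame with columns `lo`, `hi`, `weight_pct`.
#' @export
attention_report <- function(result, regions) {
  stopifnot(inherits(result, "correction_result"))
  if (is.list(regions) && !is.data.frame(regions)) {
    regions <- do.call(rbind, regions)
  }
  regions <- as.matrix(regions)
  if (ncol(regions) != 2L) {
    stop("`regions` must have two columns (lo, hi)", call. = FALSE)
  }
  freqs <- freq_axis(result$corrected)
  span <- range(freqs)
  if (any(regions[, 1] > regions[, 2])) {
    stop("region lower bounds must not exceed upper bounds", call. = FALSE)
  }
  if (any(regions[, 1] < span[1] - 1e-9) || any(regions[, 2] > span[2] + 1e-9)) {
    stop(sprintf("regions must lie within the spectrum span [%.6g, %.6g] Hz",
                 span[1], span[2]), call. = FALSE)
  }
  total <- sum(result$attention)
  pct <- vapply(seq_len(nrow(regions)), function(i) {
    inside <- freqs >= regions[i, 1] & freqs <= regions[i, 2]
    100 * sum(result$attention[inside]) / total
  }, numeric(1))
  data.frame(lo = regions[, 1], hi = regions[, 2], weight_pct = pct)
}
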