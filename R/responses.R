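#' Construct a response function
#'
#' A response function is the discrete kernel that maps the ideal (perfectly
#' shimmed) spectrum onto its distorted counterpart by convolution. It is a
#' vector of `N` real amplitudes at frequency step `delta_f`, with the kernel
#' index `(N - 1) / 2` (0-based) aligned with zero frequency shift.
#'
#' A well-chosen window length makes the kernel decay to zero at both ends;
#' endpoint amplitudes above `endpoint_tolerance` of the kernel maximum
#' trigger a warning, since they indicate the window `W` is too small.
#'
#' @param values Numeric vector of odd length `N`, all finite.
#' @param delta_f Frequency step (Hz, > 0).
#' @param setting Optional [shim_setting] the kernel was measured at.
#' @param residual_rms Optional relative fit residual recorded by
#'   [extract_response()].
#' @param endpoint_tolerance Maximum allowed ratio of `|values|` at the ends
#'   to `max(|values|)` before a warning is emitted (default 0.05).
#' @return An object of class `response_function`.
#' @export
response_function <- function(values, delta_f, setting = NULL,
                              residual_rms = NA_real_,
                              endpoint_tolerance = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L || n %% 2L == 0L) {
    stop("response length must be odd and >= 1", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("response values must be finite", call. = FALSE)
  }
  if (!is.finite(delta_f) || delta_f <= 0) {
    stop("`delta_f` must be > 0", call. = FALSE)
  }
  mx <- max(abs(values))
  if (n >= 3L && mx > 0 &&
      (abs(values[1]) >= endpoint_tolerance * mx ||
       abs(values[n]) >= endpoint_tolerance * mx)) {
    warning(sprintf(
      "response endpoints are %.3g/%.3g of the maximum (tolerance %.3g); window may be too narrow",
      abs(values[1]) / mx, abs(values[n]) / mx, endpoint_tolerance),
      call. = FALSE)
  }
  structure(
    list(values = values, delta_f = delta_f, setting = setting,
         center_index = (n - 1L) %/% 2L, residual_rms = residual_rms),
    class = "response_function"
  )
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function> N=%d, delta_f=%.4g Hz, sum=%.4g\n",
              length(x$values), x$delta_f, sum(x$values)))
  invisible(x)
}

#' Collection of response functions on a common grid
#'
#' @param values Numeric matrix, one kernel per column (N x M).
#' @param delta_f Common frequency step (Hz).
#' @param settings Optional data.frame with columns `z1`, `z2`, one row per
#'   kernel.
#' @param grid_shape Optional integer vector `c(n1, n2)` describing the shim
#'   grid the kernels were collected on (needed by [smoothness_map()]).
#' @param residuals Optional numeric vector of per-kernel fit residuals.
#' @return An object of class `response_library`.
#' @export
response_library <- function(values, delta_f, settings = NULL,
                             grid_shape = NULL, residuals = NULL) {
  values <- as.matrix(values)
  if (nrow(values) %% 2L == 0L) {
    stop("response length (rows) must be odd", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("library values must be finite", call. = FALSE)
  }
  if (!is.null(settings) && nrow(settings) != ncol(values)) {
    stop("`settings` must have one row per kernel", call. = FALSE)
  }
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    if (length(grid_shape) != 2L || prod(grid_shape) != ncol(values)) {
      stop("`grid_shape` must multiply to the number of kernels",
           call. = FALSE)
    }
  }
  structure(
    list(values = values, delta_f = delta_f, settings = settings,
         grid_shape = grid_shape, residuals = residuals),
    class = "response_library"
  )
}

#' @export
print.response_library <- function(x, ...) {
  cat(sprintf("<response_library> %d kernels of %d points, delta_f=%.4g Hz%s\n",
              ncol(x$values), nrow(x$values), x$delta_f,
              if (is.null(x$grid_shape)) "" else
                sprintf(", grid %dx%d", x$grid_shape[1], x$grid_shape[2])))
  invisible(x)
}

#' Number of kernels in a response library
#' @param library A [response_library].
#' @return Integer count.
#' @export
library_size <- function(library) {
  stopifnot(inherits(library, "response_library"))
  ncol(library$values)
}

#' Convolve a spectrum with a response function
#'
#' Same-length discrete convolution with the kernel centered at index
#' `(N - 1) / 2`; edges are zero-padded, and the output grid is identical to
#' the input grid.
#'
#' @param spectrum A [spectrum1d].
#' @param response A [response_function] with matching `delta_f` (within 1e-9
#'   relative).
#' @return The distorted [spectrum1d].
#' @export
convolve_spectrum <- function(spectrum, response) {
  stopifnot(inherits(spectrum, "spectrum1d"),
            inherits(response, "response_function"))
  if (abs(spectrum$freq_step - response$delta_f) >
      1e-9 * response$delta_f) {
    stop(sprintf(
      "frequency step mismatch: spectrum %.9g Hz vs response %.9g Hz",
      spectrum$freq_step, response$delta_f), call. = FALSE)
  }
  out <- spectrum
  out$values <- conv_same_vec(spectrum$values, response$values)
  out
}

## Build the windowed convolution design matrix: column t (1-based) holds the
## reference spectrum shifted by (t - 1 - center) bins, restricted to rows
## `window` (global indices into `best`).
.conv_design <- function(best_values, n, window) {
  L <- length(best_values)
  center <- (n - 1L) %/% 2L
  A <- matrix(0, length(window), n)
  for (t in seq_len(n)) {
    src <- window - (t - 1L - center)
    ok <- src >= 1L & src <= L
    A[ok, t] <- best_values[src[ok]]
  }
  A
}

## Automatic fit window: centered on the distorted maximum, wide enough to
## hold every point of `best` above 0.1% of its maximum plus N-point margins.
.auto_window <- function(best_values, distorted_values, n) {
  mx <- max(best_values)
  supp <- which(best_values > 1e-3 * mx)
  width <- (supp[length(supp)] - supp[1] + 1L) + 2L * n
  center <- which.max(distorted_values)
  lo <- center - width %/% 2L
  hi <- lo + width - 1L
  L <- length(best_values)
  if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
  if (hi > L) { lo <- max(1L, lo - (hi - L)); hi <- L }
  lo:hi
}

#' Extract a response function by least-squares deconvolution
#'
#' Fits the `N` kernel values so that the convolution of the best-shimmed
#' reference spectrum with the kernel reproduces the distorted spectrum over
#' a fit window, by dense least squares (QR on the windowed system):
#' `argmin_r ||A r - d||^2 + lambda ||r||^2` with
#' `lambda = ridge * max(diag(A'A))`. With `ridge = 0` and a rank-deficient
#' system, the fit is retried once with `ridge = 1e-8` and a warning.
#'
#' @param best Best-shimmed reference [spectrum1d].
#' @param distorted Distorted [spectrum1d] on the same grid (same length,
#'   `freq_start` and `freq_step` within 1e-9 relative).
#' @param n Odd kernel length `N`.
#' @param window `"auto"` (default) or an integer vector of point indices to
#'   fit over; must cover the reference peak support plus an `N`-point margin
#'   on each side.
#' @param ridge Non-negative ridge penalty, relative to the largest diagonal
#'   entry of the normal matrix.
#' @return A [response_function] with the relative root-mean-square fit
#'   residual in `$residual_rms`.
#' @export
extract_response <- function(best, distorted, n, window = "auto",
                             ridge = 0) {
  stopifnot(inherits(best, "spectrum1d"), inherits(distorted, "spectrum1d"))
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) {
    stop("`n` must be odd and >= 1", call. = FALSE)
  }
  if (length(best$values) != length(distorted$values) ||
      abs(best$freq_step - distorted$freq_step) > 1e-9 * best$freq_step ||
      abs(best$freq_start - distorted$freq_start) >
        1e-9 * max(best$freq_step, abs(best$freq_start))) {
    stop("`best` and `distorted` must share the same frequency grid",
         call. = FALSE)
  }
  if (!is.finite(ridge) || ridge < 0) {
    stop("`ridge` must be >= 0", call. = FALSE)
  }
  if (identical(window, "auto")) {
    window <- .auto_window(best$values, distorted$values, n)
  } else {
    window <- as.integer(window)
    if (any(window < 1L) || any(window > length(best$values))) {
      stop("`window` indices out of range", call. = FALSE)
    }
    if (length(window) < n) {
      stop(sprintf("fit window of %d points is too narrow for N = %d",
                   length(window), n), call. = FALSE)
    }
  }
  A <- .conv_design(best$values, n, window)
  d <- distorted$values[window]
  scale2 <- max(colSums(A^2))
  solve_ridge <- function(lambda_rel) {
    if (lambda_rel > 0) {
      lam <- sqrt(lambda_rel * scale2)
      Aa <- rbind(A, diag(lam, n))
      da <- c(d, numeric(n))
    } else {
      Aa <- A
      da <- d
    }
    qr_ <- qr(Aa)
    if (qr_$rank < n) return(NULL)
    qr.coef(qr_, da)
  }
  r <- solve_ridge(ridge)
  if (is.null(r)) {
    if (ridge == 0) {
      warning("normal system is rank-deficient at ridge = 0; retrying with ridge = 1e-8",
              call. = FALSE)
      r <- solve_ridge(1e-8)
    }
    if (is.null(r)) {
      stop("least-squares system is ill-conditioned; increase `ridge`",
           call. = FALSE)
    }
  }
  resid <- A %*% r - d
  rel_rms <- sqrt(mean(resid^2)) / max(abs(d))
  response_function(r, best$freq_step,
                    setting = {
                      z1 <- distorted$meta$z1; z2 <- distorted$meta$z2
                      if (!is.null(z1) && !is.null(z2)) {
                        shim_setting(as.numeric(z1), as.numeric(z2))
                      } else NULL
                    },
                    residual_rms = rel_rms)
}

#' Build a response library from a directory of calibration spectra
#'
#' Reads every `calib_*.txt` spectrum in `calibration_dir` (any `*.txt`
#' except `best.txt` and files ending in `.tsv`), extracts one response
#' function per file against `best`, and assembles them into a
#' [response_library]. Per-file failures are collected; the run aborts only
#' if more than 1% of the files fail. Endpoint-tolerance violations surface
#' as warnings naming the offending setting.
#'
#' @param best Best-shimmed reference [spectrum1d].
#' @param calibration_dir Directory of calibration spectrum text files.
#' @param plan A [resolution_plan] providing `n_response` and `delta_f`.
#' @param ridge Passed to [extract_response()].
#' @return A [response_library] with settings read from the file headers and
#'   the grid shape inferred from them when complete.
#' @export
build_library <- function(best, calibration_dir, plan, ridge = 0) {
  stopifnot(inherits(best, "spectrum1d"), inherits(plan, "resolution_plan"))
  files <- sort(list.files(calibration_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  files <- files[basename(files) != "best.txt"]
  if (length(files) == 0L) {
    stop(sprintf("no calibration spectra found in '%s'", calibration_dir),
         call. = FALSE)
  }
  n <- plan$n_response
  vals <- matrix(NA_real_, n, length(files))
  z1 <- z2 <- resid <- rep(NA_real_, length(files))
  failures <- character(0)
  for (i in seq_along(files)) {
    res <- tryCatch({
      sp <- read_spectrum_text(files[i])
      r <- extract_response(best, sp, n, ridge = ridge)
      list(r = r, sp = sp)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", basename(files[i]), res))
      next
    }
    vals[, i] <- res$r$values
    resid[i] <- res$r$residual_rms
    if (!is.null(res$sp$meta$z1)) z1[i] <- as.numeric(res$sp$meta$z1)
    if (!is.null(res$sp$meta$z2)) z2[i] <- as.numeric(res$sp$meta$z2)
  }
  if (length(failures) > 0.01 * length(files)) {
    stop(sprintf("library build failed for %d of %d spectra:\n%s",
                 length(failures), length(files),
                 paste(utils::head(failures, 5), collapse = "\n")),
         call. = FALSE)
  }
  ok <- !is.na(vals[1, ])
  vals <- vals[, ok, drop = FALSE]
  settings <- NULL
  grid_shape <- NULL
  if (!anyNA(z1[ok]) && !anyNA(z2[ok])) {
    settings <- data.frame(z1 = z1[ok], z2 = z2[ok])
    n1 <- length(unique(settings$z1))
    n2 <- length(unique(settings$z2))
    if (n1 * n2 == nrow(settings)) grid_shape <- c(n1, n2)
  }
  response_library(vals, plan$delta_f, settings = settings,
                   grid_shape = grid_shape, residuals = resid[ok])
}

#' Map of local response variation across the shim grid
#'
#' For each grid node, the mean Euclidean distance between its kernel and its
#' 4-neighbors' kernels. Smoothly varying responses produce a smooth, low
#' map; isolated spikes flag extraction failures. Intended for QC plotting.
#'
#' @param library A [response_library] carrying `grid_shape`.
#' @return A numeric matrix of shape `grid_shape`.
#' @export
smoothness_map <- function(library) {
  stopifnot(inherits(library, "response_library"))
  if (is.null(library$grid_shape)) {
    stop("library carries no grid-shape metadata", call. = FALSE)
  }
  n1 <- library$grid_shape[1]
  n2 <- library$grid_shape[2]
  # kernels are stored z2-fastest (row-major over z1 rows)
  out <- matrix(0, n1, n2)
  kernel <- function(i, j) library$values[, (i - 1L) * n2 + j]
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      k0 <- kernel(i, j)
      d <- numeric(0)
      if (i > 1L) d <- c(d, sqrt(sum((k0 - kernel(i - 1L, j))^2)))
      if (i < n1) d <- c(d, sqrt(sum((k0 - kernel(i + 1L, j))^2)))
      if (j > 1L) d <- c(d, sqrt(sum((k0 - kernel(i, j - 1L))^2)))
      if (j < n2) d <- c(d, sqrt(sum((k0 - kernel(i, j + 1L))^2)))
      out[i, j] <- mean(d)
    }
  }
  out
}

#' Write a response library to a plain-text TSV file
#'
#' Header lines (`# key: value`) record the frequency step, kernel length and
#' grid shape; each subsequent row holds `z1`, `z2`, the fit residual and the
#' `N` kernel values, tab-separated at full double precision.
#'
#' @param library A [response_library].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "response_library"))
  n <- nrow(library$values)
  m <- ncol(library$values)
  header <- c(
    sprintf("# delta_f: %.17g", library$delta_f),
    sprintf("# n_response: %d", n),
    if (!is.null(library$grid_shape))
      sprintf("# grid_shape: %d %d", library$grid_shape[1],
              library$grid_shape[2])
  )
  z1 <- if (is.null(library$settings)) rep(NA_real_, m) else library$settings$z1
  z2 <- if (is.null(library$settings)) rep(NA_real_, m) else library$settings$z2
  resid <- if (is.null(library$residuals)) rep(NA_real_, m) else
    library$residuals
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  rows <- vapply(seq_len(m), function(i) {
    paste(c(fmt(z1[i]), fmt(z2[i]), fmt(resid[i]),
            sprintf("%.17g", library$values[, i])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a response library written by [write_library()]
#'
#' @param path Path to the TSV library file.
#' @return A [response_library].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("library file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  data_lines <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      m <- regmatches(body, regexec("^([^:]+):(.*)$", body))[[1]]
      if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
    } else {
      data_lines <- c(data_lines, ln)
    }
  }
  delta_f <- as.numeric(meta[["delta_f"]])
  n <- as.integer(meta[["n_response"]])
  if (!is.finite(delta_f) || is.na(n)) {
    stop("library file lacks delta_f / n_response header", call. = FALSE)
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  m <- length(parts)
  vals <- matrix(0, n, m)
  z1 <- z2 <- resid <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    fields <- trimws(parts[[i]])
    if (length(fields) != n + 3L) {
      stop(sprintf("library row %d has %d fields; expected %d", i,
                   length(fields), n + 3L), call. = FALSE)
    }
    # the three leading metadata fields may legitimately be NA
    meta3 <- suppressWarnings(as.numeric(fields[1:3]))
    kernel <- as.numeric(fields[-(1:3)])
    if (anyNA(kernel)) {
      stop(sprintf("library row %d contains non-numeric kernel values", i),
           call. = FALSE)
    }
    z1[i] <- meta3[1]; z2[i] <- meta3[2]; resid[i] <- meta3[3]
    vals[, i] <- kernel
  }
  settings <- if (anyNA(z1) || anyNA(z2)) NULL else data.frame(z1 = z1, z2 = z2)
  grid_shape <- NULL
  if (!is.null(meta[["grid_shape"]])) {
    grid_shape <- as.integer(strsplit(meta[["grid_shape"]], " +")[[1]])
  }
  response_library(vals, delta_f, settings = settings,
                   grid_shape = grid_shape,
                   residuals = if (anyNA(resid)) NULL else resid)
}
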