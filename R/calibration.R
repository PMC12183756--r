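#' Shim setting of a simulated acquisition
#'
#' Currents in the first- and second-order axial shim coils, in simulator
#' units. `(0, 0)` is the best-shimmed state.
#'
#' @param z1,z2 Finite coil currents (arbitrary units).
#' @return An object of class `shim_setting`.
#' @export
shim_setting <- function(z1, z2) {
  if (!is.finite(z1) || !is.finite(z2)) {
    stop("`z1` and `z2` must be finite", call. = FALSE)
  }
  structure(list(z1 = as.numeric(z1), z2 = as.numeric(z2)),
            class = "shim_setting")
}

#' Rectangular grid of shim settings
#'
#' @param z1_start,z1_stop,z1_step First-axis range and step (step > 0,
#'   stop >= start).
#' @param z2_start,z2_stop,z2_step Second-axis range and step.
#' @return An object of class `calibration_grid` with derived counts `n1`,
#'   `n2`.
#' @examples
#' g <- calibration_grid(8768, 8968, 2, -397, -197, 2)
#' g$n1 * g$n2  # 10201
#' @export
calibration_grid <- function(z1_start, z1_stop, z1_step,
                             z2_start, z2_stop, z2_step) {
  for (s in list(z1_step, z2_step)) {
    if (!is.finite(s) || s <= 0) stop("grid steps must be > 0", call. = FALSE)
  }
  if (z1_stop < z1_start || z2_stop < z2_start) {
    stop("grid stop must be >= start", call. = FALSE)
  }
  n1 <- floor((z1_stop - z1_start) / z1_step + 1e-9) + 1L
  n2 <- floor((z2_stop - z2_start) / z2_step + 1e-9) + 1L
  structure(
    list(z1_start = z1_start, z1_stop = z1_stop, z1_step = z1_step,
         z2_start = z2_start, z2_stop = z2_stop, z2_step = z2_step,
         n1 = as.integer(n1), n2 = as.integer(n2)),
    class = "calibration_grid"
  )
}

#' Enumerate all settings of a calibration grid
#'
#' Row-major order: `z1` is the slow axis, `z2` the fast one.
#'
#' @param grid A [calibration_grid].
#' @return A data.frame with columns `z1`, `z2` and `grid$n1 * grid$n2` rows.
#' @export
grid_settings <- function(grid) {
  stopifnot(inherits(grid, "calibration_grid"))
  if (grid$n1 < 1L || grid$n2 < 1L) {
    stop("degenerate calibration grid", call. = FALSE)
  }
  z1 <- grid$z1_start + (seq_len(grid$n1) - 1L) * grid$z1_step
  z2 <- grid$z2_start + (seq_len(grid$n2) - 1L) * grid$z2_step
  data.frame(
    z1 = rep(z1, each = grid$n2),
    z2 = rep(z2, times = grid$n1)
  )
}

#' Axial shim-field model for the calibration simulator
#'
#' The frequency offset experienced by a spin at normalized column position
#' `z` in `[-1, 1]` is modelled with the first two Legendre profiles:
#' `delta(z) = kappa1 * z1 * z + kappa2 * z2 * (3 z^2 - 1) / 2`.
#' The simulated response function is the density of `delta(z)` under uniform
#' `z`, smoothed by the natural Lorentzian line of half-width `w_nat`.
#'
#' Defaults are scaled so the corners of a +/-80-unit grid give a response
#' about 13 Hz wide, comfortably inside a 21 Hz response window at a 0.34 Hz
#' frequency step. The default natural half-width corresponds to a
#' calibration singlet with a ~20 s transverse relaxation time
#' (`1 / (pi * T2)` ~ 0.016 Hz), which contributes almost nothing to the
#' observed linewidth - the property a calibration sample is chosen for.
#'
#' @param kappa1,kappa2 Coupling of shim units to Hz for the linear/quadratic
#'   profile.
#' @param w_nat Natural Lorentzian half-width at half-maximum (Hz, > 0).
#' @param omega_s Singlet frequency (Hz).
#' @param height Singlet peak height (arbitrary units).
#' @return An object of class `field_model`.
#' @export
field_model <- function(kappa1 = 0.08, kappa2 = 0.035, w_nat = 0.016,
                        omega_s = 0, height = 100) {
  if (!is.finite(kappa1) || !is.finite(kappa2)) {
    stop("`kappa1`, `kappa2` must be finite", call. = FALSE)
  }
  if (!is.finite(w_nat) || w_nat <= 0) {
    stop("`w_nat` must be > 0", call. = FALSE)
  }
  structure(
    list(kappa1 = kappa1, kappa2 = kappa2, w_nat = w_nat,
         omega_s = omega_s, height = height),
    class = "field_model"
  )
}

## Number of uniform z samples used for the density quadrature.
.sim_nz <- 2e5
## Fine-grid oversampling factor relative to delta_f.
.sim_fine <- 8L

#' Simulate the response function of a shim setting
#'
#' Computes the distribution of the field-model frequency offset over the
#' sample column by dense quadrature (2e5 uniform `z` samples histogrammed at
#' `delta_f / 8`), convolves it with the discretized unit-area natural
#' Lorentzian, box-averages onto the `N`-point `delta_f` grid centered at
#' zero frequency shift, and renormalizes to unit sum. Errors if more than
#' 0.1% of the mass falls outside the `N`-point window, which signals that
#' the response window `W` was chosen too small for this setting.
#'
#' @param setting A [shim_setting].
#' @param model A [field_model].
#' @param delta_f Frequency step (Hz, > 0).
#' @param n Odd number of kernel points.
#' @return A [response_function] with unit sum and the setting attached.
#' @export
simulate_response <- function(setting, model, delta_f, n) {
  stopifnot(inherits(setting, "shim_setting"), inherits(model, "field_model"))
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("`n` must be odd and >= 1", call. = FALSE)
  if (!is.finite(delta_f) || delta_f <= 0) {
    stop("`delta_f` must be > 0", call. = FALSE)
  }
  h <- delta_f / .sim_fine
  half_fine <- 4L * n          # window half-width in fine bins
  ext <- 3L * half_fine        # extended grid for overflow detection

  nz <- .sim_nz
  z <- -1 + (seq_len(nz) - 0.5) * (2 / nz)
  delta <- model$kappa1 * setting$z1 * z +
    model$kappa2 * setting$z2 * (3 * z^2 - 1) / 2
  idx <- as.integer(floor(delta / h + 0.5))
  inside <- abs(idx) <= ext
  dens <- numeric(2L * ext + 1L)
  tb <- tabulate(idx[inside] + ext + 1L, nbins = 2L * ext + 1L)
  dens <- tb / nz

  # truncated, unit-sum natural Lorentzian kernel on the fine window
  kf <- seq.int(-half_fine, half_fine) * h
  lor <- 1 / (model$w_nat^2 + kf^2)
  lor <- lor / sum(lor)
  smoothed <- conv_same_vec(dens, lor)

  # symmetric box average: 7 interior fine bins plus half of the two edge bins
  centers <- seq.int(-(n - 1L) / 2L, (n - 1L) / 2L)
  coarse <- vapply(centers, function(t) {
    i0 <- 8L * t + ext + 1L   # fine index of the coarse-bin center
    sum(smoothed[(i0 - 3L):(i0 + 3L)]) +
      0.5 * smoothed[i0 - 4L] + 0.5 * smoothed[i0 + 4L]
  }, numeric(1))

  mass_in <- sum(coarse)
  if (1 - mass_in >= 1e-3) {
    stop(sprintf(
      "response overflows the %d-point window (%.2g of mass outside); increase W or N",
      n, 1 - mass_in), call. = FALSE)
  }
  response_function(coarse / mass_in, delta_f, setting = setting)
}

#' Simulated best-shimmed reference singlet
#'
#' The pure natural Lorentzian line of the calibration sample, evaluated on a
#' grid of `n_points` centered so the singlet frequency falls exactly on a
#' grid point. This is the simulator's stand-in for the measured best-shimmed
#' spectrum and serves as the deconvolution reference in
#' [extract_response()].
#'
#' @param model A [field_model].
#' @param delta_f Frequency step (Hz).
#' @param n_points Number of points (>= 128).
#' @return A [spectrum1d].
#' @export
simulate_best_spectrum <- function(model, delta_f, n_points) {
  stopifnot(inherits(model, "field_model"))
  n_points <- as.integer(n_points)
  if (n_points < 128L) stop("`n_points` must be >= 128", call. = FALSE)
  start <- model$omega_s - (n_points %/% 2L) * delta_f
  freqs <- start + (seq_len(n_points) - 1L) * delta_f
  vals <- model$height * model$w_nat^2 /
    (model$w_nat^2 + (freqs - model$omega_s)^2)
  spectrum1d(start, delta_f, vals,
             meta = list(z1 = 0, z2 = 0, kind = "best"))
}

#' Simulate one mis-shimmed calibration spectrum
#'
#' The best-shimmed singlet convolved with the setting's simulated response
#' function, plus white Gaussian noise. Reproducible under `seed`.
#'
#' @inheritParams simulate_response
#' @param delta_f Frequency step (Hz).
#' @param n_points Number of spectrum points (>= 128).
#' @param n_response Odd response-kernel length (points).
#' @param noise_sd Gaussian noise standard deviation (0 disables noise).
#' @param seed Integer seed for the noise.
#' @return A [spectrum1d] with `z1`, `z2` recorded in `$meta`.
#' @export
simulate_calibration_spectrum <- function(setting, model, delta_f, n_points,
                                          n_response, noise_sd = 0,
                                          seed = 1L) {
  best <- simulate_best_spectrum(model, delta_f, n_points)
  resp <- simulate_response(setting, model, delta_f, n_response)
  vals <- conv_same_vec(best$values, resp$values)
  if (noise_sd > 0) {
    vals <- vals + .with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  }
  spectrum1d(best$freq_start, delta_f, vals,
             meta = list(z1 = setting$z1, z2 = setting$z2))
}

## Evaluate `expr` under a temporary RNG seed, restoring the global state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Per-spectrum seed derived from a master seed and a grid index.
.derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Simulate a full calibration data set
#'
#' Emulates the calibration experiment: one best-shimmed reference plus one
#' mis-shimmed spectrum per grid setting, with the ground-truth response
#' functions retained. Optionally writes everything as spectrum text files
#' plus a plain-text response-library sidecar, the on-disk layout consumed by
#' [build_library()].
#'
#' @param grid A [calibration_grid].
#' @param model A [field_model].
#' @param plan A [resolution_plan].
#' @param n_points Points per calibration spectrum.
#' @param noise_sd Noise standard deviation per spectrum.
#' @param seed Master seed; per-spectrum seeds are derived from it and the
#'   grid index so parallel regeneration is reproducible.
#' @param dir Optional output directory for text files.
#' @return A list with `best` ([spectrum1d]), `spectra` (list of
#'   [spectrum1d]), `truth` (a [response_library] of ground-truth kernels),
#'   and `settings` (data.frame).
#' @export
simulate_calibration_set <- function(grid, model, plan, n_points = 1024,
                                     noise_sd = 0, seed = 1L, dir = NULL) {
  stopifnot(inherits(plan, "resolution_plan"))
  settings <- grid_settings(grid)
  m <- nrow(settings)
  best <- simulate_best_spectrum(model, plan$delta_f, n_points)
  spectra <- vector("list", m)
  truth <- matrix(0, plan$n_response, m)
  for (i in seq_len(m)) {
    st <- shim_setting(settings$z1[i], settings$z2[i])
    resp <- simulate_response(st, model, plan$delta_f, plan$n_response)
    truth[, i] <- resp$values
    vals <- conv_same_vec(best$values, resp$values)
    if (noise_sd > 0) {
      vals <- vals + .with_seed(.derive_seed(seed, i),
                                stats::rnorm(n_points, 0, noise_sd))
    }
    spectra[[i]] <- spectrum1d(best$freq_start, plan$delta_f, vals,
                               meta = list(z1 = st$z1, z2 = st$z2))
  }
  lib <- response_library(truth, plan$delta_f, settings = settings,
                          grid_shape = c(grid$n1, grid$n2))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectrum_text(best, file.path(dir, "best.txt"))
    for (i in seq_len(m)) {
      write_spectrum_text(spectra[[i]],
                          file.path(dir, sprintf("calib_%05d.txt", i)))
    }
    write_library(lib, file.path(dir, "truth_library.tsv"))
  }
  list(best = best, spectra = spectra, truth = lib, settings = settings)
}
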