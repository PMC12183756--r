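#' Lorentzian-Gaussian peak profile
#'
#' Evaluates the mixed lineshape
#' `f(w) = (1 - gamma) H w0^2 / (w0^2 + (w - omega0)^2) +
#'  gamma H exp(-(w - omega0)^2 / (2 sigma^2))`
#' with the two component widths tied so both halves share the same FWHM:
#' `w0 = sigma * sqrt(2 ln 2)`. At the center the value is exactly `H`; at
#' `omega0 +/- w0` it is `H / 2` for either pure lineshape.
#'
#' @param grid Numeric vector of frequencies (Hz).
#' @param height Total peak height `H` (> 0).
#' @param gamma Gaussian fraction in `[0, 1]`.
#' @param omega0 Center frequency (Hz).
#' @param w Half-width at half-maximum of the Lorentzian part (Hz, > 0).
#' @return Numeric vector of intensities on `grid`.
#' @export
lg_peak <- function(grid, height, gamma, omega0, w) {
  if (!is.finite(height) || height <= 0) stop("`height` must be > 0", call. = FALSE)
  if (!is.finite(w) || w <= 0) stop("`w` must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  sigma <- w / sqrt(2 * log(2))
  d <- grid - omega0
  (1 - gamma) * height * w^2 / (w^2 + d^2) +
    gamma * height * exp(-d^2 / (2 * sigma^2))
}

#' Binomial multiplet component weights
#'
#' Relative heights of the `m` components of a first-order multiplet under
#' the weak-coupling approximation: binomial coefficients `C(m-1, k)`,
#' normalized to unit sum so a singlet has weight 1.
#'
#' @param m Multiplicity (integer 1..7).
#' @return Numeric vector of `m` weights summing to 1.
#' @examples
#' multiplet_heights(3)  # 0.25 0.50 0.25
#' @export
multiplet_heights <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > 7L) {
    stop("`m` must be an integer in 1..7", call. = FALSE)
  }
  choose(m - 1L, 0:(m - 1L)) / 2^(m - 1L)
}

#' Specification of one synthetic multiplet
#'
#' @param m Multiplicity (1..7).
#' @param j1 Primary coupling constant (Hz, component spacing).
#' @param j2 Secondary coupling constant (Hz), used when `secondary_split`.
#' @param w_m Component width draw (Hz).
#' @param h_i Relative intensity (proton-count analogue).
#' @param h_m Multiplet height factor.
#' @param gamma Gaussian fraction shared by all components.
#' @param omega0 Multiplet center (Hz).
#' @param secondary_split Whether `j2` further splits every component into a
#'   half-weight doublet.
#' @return An object of class `multiplet_spec`.
#' @export
multiplet_spec <- function(m, j1, j2, w_m, h_i, h_m, gamma, omega0,
                           secondary_split = FALSE) {
  m <- as.integer(m)
  if (m < 1L || m > 7L) stop("`m` must be in 1..7", call. = FALSE)
  vals <- c(j1 = j1, j2 = j2, w_m = w_m, h_i = h_i, h_m = h_m,
            gamma = gamma, omega0 = omega0)
  if (!all(is.finite(vals))) stop("multiplet parameters must be finite", call. = FALSE)
  structure(
    list(m = m, j1 = j1, j2 = j2, w_m = w_m, h_i = h_i, h_m = h_m,
         gamma = gamma, omega0 = omega0,
         secondary_split = isTRUE(secondary_split)),
    class = "multiplet_spec"
  )
}

#' Render one multiplet onto a frequency grid
#'
#' Places `m` equidistant, equally wide Lorentzian-Gaussian components at
#' `omega0 + (k - (m - 1)/2) * j1` with heights
#' `h_b[k] * h_i * h_m * h_s` and shared width `w = w_m * w_s`. When
#' `secondary_split` is set, each component is replaced by two half-weight
#' lines `j2` apart (the tensor split from a second coupling). Components
#' whose centers fall off the grid still contribute their tails, with a
#' warning.
#'
#' @param grid Numeric frequency axis (Hz).
#' @param spec A [multiplet_spec].
#' @param w_s Spectrum-wide width factor.
#' @param h_s Spectrum-wide height factor.
#' @return Numeric vector of intensities on `grid`.
#' @export
render_multiplet <- function(grid, spec, w_s, h_s) {
  stopifnot(inherits(spec, "multiplet_spec"))
  w <- spec$w_m * w_s
  if (!is.finite(w) || w <= 0) stop("component width must be > 0", call. = FALSE)
  hb <- multiplet_heights(spec$m)
  centers <- spec$omega0 + (seq_len(spec$m) - 1 - (spec$m - 1) / 2) * spec$j1
  heights <- hb * spec$h_i * spec$h_m * h_s
  if (spec$secondary_split) {
    centers <- c(centers - spec$j2 / 2, centers + spec$j2 / 2)
    heights <- c(heights / 2, heights / 2)
  }
  if (any(centers < grid[1] | centers > grid[length(grid)])) {
    warning("multiplet component centers fall outside the frequency grid; tails clipped",
            call. = FALSE)
  }
  out <- numeric(length(grid))
  for (k in seq_along(centers)) {
    out <- out + lg_peak(grid, heights[k], spec$gamma, centers[k], w)
  }
  out
}

#' Sampling configuration for synthetic training spectra
#'
#' Defines the parameter ranges from which clean synthetic spectra are drawn:
#' 2-5 multiplets per spectrum, centers within `+/-omega0_range` Hz (clipped
#' to 90% of the grid half-span when the grid is narrower), couplings 0-15
#' Hz, per-multiplet widths 1-2 Hz scaled by a spectrum-wide factor 0.2-1 (so
#' component half-widths span 0.2-2 Hz), heights combining binomial weights
#' with intensity 1-3 and height factors 0.5-4 (multiplet) and 0.5-2
#' (spectrum), a per-multiplet Gaussian fraction in `[0, 1]`, and white noise
#' with a standard deviation drawn uniformly from `[0, noise_max]`.
#' Multiplicities 1..7 are drawn with weights favoring low multiplicities,
#' and each multiplet receives a secondary doublet split with probability
#' 0.5.
#'
#' @param n_points Spectrum length in points (>= 128; 2048 for full-scale
#'   training).
#' @param delta_f Frequency step (Hz).
#' @param M_range Integer range of multiplets per spectrum.
#' @param omega0_range Half-range of multiplet centers (Hz).
#' @param j_range Coupling-constant range (Hz).
#' @param w_m_range Per-multiplet component width range (Hz).
#' @param w_s_range Spectrum width-factor range.
#' @param h_i_range Relative-intensity range.
#' @param h_m_range Multiplet height-factor range.
#' @param h_s_range Spectrum height-factor range.
#' @param gamma_range Gaussian-fraction range.
#' @param noise_max Upper bound of the noise standard deviation.
#' @param m_weights Sampling weights for multiplicities 1..7.
#' @param split_prob Probability of the secondary `j2` split per multiplet.
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(n_points = 2048L, delta_f = 0.3406,
                            M_range = c(2L, 5L), omega0_range = 279.02,
                            j_range = c(0, 15), w_m_range = c(1, 2),
                            w_s_range = c(0.2, 1), h_i_range = c(1, 3),
                            h_m_range = c(0.5, 4), h_s_range = c(0.5, 2),
                            gamma_range = c(0, 1), noise_max = 0.02,
                            m_weights = c(0.30, 0.30, 0.20, 0.10,
                                          0.05, 0.03, 0.02),
                            split_prob = 0.5) {
  n_points <- as.integer(n_points)
  if (n_points < 128L) stop("`n_points` must be >= 128", call. = FALSE)
  if (!is.finite(delta_f) || delta_f <= 0) stop("`delta_f` must be > 0", call. = FALSE)
  if (length(m_weights) != 7L || any(m_weights < 0) || sum(m_weights) <= 0) {
    stop("`m_weights` must be 7 non-negative weights", call. = FALSE)
  }
  if (noise_max < 0) stop("`noise_max` must be >= 0", call. = FALSE)
  structure(
    list(n_points = n_points, delta_f = delta_f,
         M_range = as.integer(M_range), omega0_range = omega0_range,
         j_range = j_range, w_m_range = w_m_range, w_s_range = w_s_range,
         h_i_range = h_i_range, h_m_range = h_m_range,
         h_s_range = h_s_range, gamma_range = gamma_range,
         noise_max = noise_max, m_weights = m_weights / sum(m_weights),
         split_prob = split_prob),
    class = "sampling_config"
  )
}

## Frequency axis of the generation grid, centered on 0 Hz.
.config_grid <- function(config) {
  start <- -(config$n_points - 1) / 2 * config$delta_f
  start + (seq_len(config$n_points) - 1L) * config$delta_f
}

## Effective omega0 half-range: clipped to 90% of the grid half-span.
.effective_omega0 <- function(config) {
  half_span <- (config$n_points - 1) / 2 * config$delta_f
  min(config$omega0_range, 0.9 * half_span)
}

#' Draw one clean synthetic spectrum
#'
#' Draws the number of multiplets, the spectrum-scope factors, and the
#' per-multiplet parameters from the configured ranges, renders the sum of
#' multiplets on the generation grid, and returns it together with the full
#' parameter record. All draws come from R's global RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param config A [sampling_config].
#' @return A list with `values` (clean spectrum), `grid` (frequency axis,
#'   Hz), and `record` (a data.frame of per-multiplet parameter draws plus
#'   attributes `M`, `w_s`, `h_s`).
#' @export
sample_spectrum <- function(config) {
  stopifnot(inherits(config, "sampling_config"))
  grid <- .config_grid(config)
  M <- sample.int(config$M_range[2] - config$M_range[1] + 1L, 1L) +
    config$M_range[1] - 1L
  w_s <- stats::runif(1, config$w_s_range[1], config$w_s_range[2])
  h_s <- stats::runif(1, config$h_s_range[1], config$h_s_range[2])
  om_half <- .effective_omega0(config)
  rec <- data.frame(
    m = sample(1:7, M, replace = TRUE, prob = config$m_weights),
    omega0 = stats::runif(M, -om_half, om_half),
    j1 = stats::runif(M, config$j_range[1], config$j_range[2]),
    j2 = stats::runif(M, config$j_range[1], config$j_range[2]),
    w_m = stats::runif(M, config$w_m_range[1], config$w_m_range[2]),
    h_i = stats::runif(M, config$h_i_range[1], config$h_i_range[2]),
    h_m = stats::runif(M, config$h_m_range[1], config$h_m_range[2]),
    gamma = stats::runif(M, config$gamma_range[1], config$gamma_range[2]),
    secondary_split = stats::runif(M) < config$split_prob
  )
  values <- numeric(config$n_points)
  for (i in seq_len(M)) {
    sp <- multiplet_spec(rec$m[i], rec$j1[i], rec$j2[i], rec$w_m[i],
                         rec$h_i[i], rec$h_m[i], rec$gamma[i], rec$omega0[i],
                         rec$secondary_split[i])
    values <- values + suppressWarnings(render_multiplet(grid, sp, w_s, h_s))
  }
  attr(rec, "M") <- M
  attr(rec, "w_s") <- w_s
  attr(rec, "h_s") <- h_s
  list(values = values, grid = grid, record = rec)
}

#' Form one hybrid training example
#'
#' Convolves a clean synthetic spectrum with a uniformly chosen kernel from
#' the response library and adds white Gaussian noise whose standard
#' deviation is drawn uniformly from `[0, noise_max]`.
#'
#' @param s_trg Numeric vector: the clean target spectrum.
#' @param library A non-empty [response_library] on the generation grid's
#'   frequency step.
#' @param noise_max Upper bound of the noise standard deviation.
#' @return A list with `s_trg`, `s_inp` (distorted noisy input), `r_trg`
#'   (the kernel applied), `response_index`, and `noise_sd`.
#' @export
make_training_example <- function(s_trg, library, noise_max = 0.02) {
  stopifnot(inherits(library, "response_library"))
  if (library_size(library) < 1L) {
    stop("response library is empty", call. = FALSE)
  }
  idx <- sample.int(library_size(library), 1L)
  r <- library$values[, idx]
  s_inp <- conv_same_vec(s_trg, r)
  noise_sd <- if (noise_max > 0) stats::runif(1, 0, noise_max) else 0
  if (noise_sd > 0) {
    s_inp <- s_inp + stats::rnorm(length(s_inp), 0, noise_sd)
  }
  list(s_trg = s_trg, s_inp = s_inp, r_trg = r,
       response_index = idx, noise_sd = noise_sd)
}

#' Generate a batch of hybrid training examples
#'
#' Draws `k` fresh clean spectra and their distorted noisy counterparts.
#' Every call consumes new RNG draws, so successive batches are never reused
#' (online learning).
#'
#' @param config A [sampling_config].
#' @param library A [response_library].
#' @param k Batch size.
#' @return A list of matrices `s_trg` (L x k), `s_inp` (L x k), `r_trg`
#'   (N x k).
#' @export
generate_batch <- function(config, library, k) {
  stopifnot(inherits(config, "sampling_config"),
            inherits(library, "response_library"))
  k <- as.integer(k)
  L <- config$n_points
  n <- nrow(library$values)
  s_trg <- matrix(0, L, k)
  r_trg <- matrix(0, n, k)
  idx <- sample.int(library_size(library), k, replace = TRUE)
  for (i in seq_len(k)) {
    s_trg[, i] <- sample_spectrum(config)$values
    r_trg[, i] <- library$values[, idx[i]]
  }
  s_inp <- conv_same_batch(s_trg, r_trg)
  noise_sd <- stats::runif(k, 0, config$noise_max)
  if (config$noise_max > 0) {
    s_inp <- s_inp + matrix(stats::rnorm(L * k), L, k) *
      rep(noise_sd, each = L)
  }
  list(s_trg = s_trg, s_inp = s_inp, r_trg = r_trg)
}

#' Impulse response library (identity distortion)
#'
#' A library whose every kernel is a centered unit impulse, so convolution
#' leaves spectra unchanged. Useful as a null model in tests and sanity
#' checks.
#'
#' @param n Odd kernel length.
#' @param delta_f Frequency step (Hz).
#' @param m Number of (identical) kernels.
#' @return A [response_library].
#' @export
impulse_library <- function(n, delta_f, m = 1L) {
  n <- as.integer(n)
  if (n %% 2L == 0L) stop("`n` must be odd", call. = FALSE)
  v <- numeric(n)
  v[(n - 1L) %/% 2L + 1L] <- 1
  response_library(matrix(v, n, m), delta_f)
}
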