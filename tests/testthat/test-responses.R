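test_that("same-mode convolution matches the direct-sum oracle", {
  set.seed(31)
  s <- lorentzian_spectrum(n = 128L, delta_f = 0.5)
  for (n in c(1L, 5L, 21L)) {
    r_vals <- stats::rnorm(n)
    r <- response_function(r_vals, 0.5, endpoint_tolerance = Inf)
    got <- convolve_spectrum(s, r)$values
    expect_equal(got, conv_oracle(s$values, r_vals), tolerance = 1e-12)
  }
})

test_that("impulse and shifted-impulse kernels behave as identity and shift", {
  s <- lorentzian_spectrum(n = 64L, delta_f = 0.5)
  imp <- numeric(9); imp[5] <- 1
  expect_equal(convolve_spectrum(s, response_function(imp, 0.5))$values,
               s$values, tolerance = 1e-14)

  shifted <- numeric(9); shifted[6] <- 1  # one bin right of center
  got <- convolve_spectrum(s, response_function(shifted, 0.5))$values
  expect_equal(got[2:64], s$values[1:63], tolerance = 1e-14)

  bad_step <- spectrum1d(0, 0.7, s$values)
  expect_error(convolve_spectrum(bad_step, response_function(imp, 0.5)),
               "mismatch")
})

test_that("deconvolving a spectrum against itself gives a unit impulse", {
  best <- lorentzian_spectrum(n = 512L, delta_f = 0.34, w = 0.8, height = 50)
  r <- extract_response(best, best, 21L)
  expected <- numeric(21); expected[11] <- 1
  expect_equal(r$values, expected, tolerance = 1e-6)
  expect_lt(r$residual_rms, 1e-10)
})

test_that("forward convolution then extraction recovers an asymmetric kernel", {
  best <- lorentzian_spectrum(n = 512L, delta_f = 0.34, w = 0.5, height = 50)
  set.seed(41)
  n <- 21L
  # asymmetric bump decaying to zero at both ends
  r_true <- sin(pi * (0:(n - 1)) / (n - 1))^2 * exp(seq(0, 1.5, length.out = n))
  r_true <- r_true / sum(r_true)
  distorted <- convolve_spectrum(best,
                                 response_function(r_true, 0.34,
                                                   endpoint_tolerance = Inf))
  r_hat <- extract_response(best, distorted, n)
  expect_lt(sqrt(mean((r_hat$values - r_true)^2)), 1e-6)

  # re-convolution reproduces the distorted window within the recorded
  # residual
  reconv <- convolve_spectrum(best, r_hat)
  expect_lt(max(abs(reconv$values - distorted$values)) / max(distorted$values),
            1e-6)
})

test_that("noisy extraction stays accurate with a small ridge", {
  best <- lorentzian_spectrum(n = 512L, delta_f = 0.34, w = 0.5, height = 50)
  n <- 21L
  set.seed(43)
  r_true <- stats::runif(n); r_true[c(1, n)] <- 0
  r_true <- r_true / sum(r_true)
  clean <- convolve_spectrum(best,
                             response_function(r_true, 0.34,
                                               endpoint_tolerance = Inf))
  noisy <- clean
  noisy$values <- noisy$values + stats::rnorm(512, 0, 1e-3 * max(clean$values))
  r_hat <- extract_response(best, noisy, n, ridge = 1e-6)
  expect_lt(sqrt(mean((r_hat$values - r_true)^2)), 1e-2)
})

test_that("fit residual is non-decreasing in the ridge strength", {
  best <- lorentzian_spectrum(n = 512L, delta_f = 0.34, w = 0.5, height = 50)
  set.seed(47)
  n <- 15L
  r_true <- stats::runif(n); r_true <- r_true / sum(r_true)
  distorted <- convolve_spectrum(best,
                                 response_function(r_true, 0.34,
                                                   endpoint_tolerance = Inf))
  distorted$values <- distorted$values + stats::rnorm(512, 0, 0.02)
  resids <- vapply(c(0, 1e-8, 1e-4, 1e-2, 1), function(rg) {
    # endpoint warnings are expected here: the random test kernel does not
    # decay at the window ends
    suppressWarnings(
      extract_response(best, distorted, n, ridge = rg)$residual_rms)
  }, numeric(1))
  expect_true(all(diff(resids) >= -1e-12))
})

test_that("library building recovers the simulator's ground truth", {
  dir <- withr::local_tempdir()
  plan <- resolution_plan(0.3406, 6, 0.4, 3)
  grid <- calibration_grid(-20, 20, 10, -20, 20, 10)
  fm <- field_model()
  cs <- simulate_calibration_set(grid, fm, plan, n_points = 512L, dir = dir)
  lib <- build_library(cs$best, dir, plan)
  expect_identical(library_size(lib), 25L)
  expect_equal(lib$grid_shape, c(5L, 5L))
  rms <- sqrt(colMeans((lib$values - cs$truth$values)^2))
  expect_true(all(rms < 1e-3))

  expect_error(build_library(cs$best, withr::local_tempdir(), plan),
               "no calibration spectra")
})

test_that("smoothness map is zero for identical kernels and flags outliers", {
  n <- 11L
  base <- stats::dnorm(seq(-2, 2, length.out = n))
  vals <- matrix(base, n, 9)
  lib <- response_library(vals, 0.5, grid_shape = c(3L, 3L))
  expect_equal(smoothness_map(lib), matrix(0, 3, 3))

  vals2 <- vals
  vals2[, 5] <- rev(seq_len(n)) / n  # outlier at the grid center
  lib2 <- response_library(vals2, 0.5, grid_shape = c(3L, 3L))
  m <- smoothness_map(lib2)
  expect_identical(which.max(m), 5L)

  expect_error(smoothness_map(response_library(vals, 0.5)), "grid-shape")
})

test_that("smoothly varying simulated responses yield a smooth map", {
  pre <- smoke_fixture()
  m <- smoothness_map(pre$library)
  expect_lt(max(m), 10 * stats::median(m))
})

test_that("response constructors enforce the endpoint and shape invariants", {
  expect_error(response_function(c(1, 2), 0.5), "odd")
  expect_error(response_function(c(1, NA, 1), 0.5), "finite")
  expect_warning(response_function(c(0.5, 1, 0.5), 0.5), "window")
  expect_silent(response_function(c(0.001, 1, 0.001), 0.5))
})
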