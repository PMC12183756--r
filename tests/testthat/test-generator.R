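test_that("the mixed lineshape obeys its center and half-height identities", {
  grid <- seq(-50, 50, by = 0.1)
  set.seed(51)
  for (i in 1:20) {
    H <- stats::runif(1, 0.1, 10)
    gamma <- stats::runif(1)
    w <- stats::runif(1, 0.2, 2)
    omega0 <- stats::runif(1, -20, 20)
    # value H at the center for any mixture
    expect_equal(lg_peak(omega0, H, gamma, omega0, w), H, tolerance = 1e-12)
    # pure Lorentzian: half height at omega0 +/- w
    expect_equal(lg_peak(omega0 + w, H, 0, omega0, w), H / 2,
                 tolerance = 1e-12)
    expect_equal(lg_peak(omega0 - w, H, 0, omega0, w), H / 2,
                 tolerance = 1e-12)
    # pure Gaussian: half height at omega0 + sigma * sqrt(2 ln 2) = omega0 + w
    expect_equal(lg_peak(omega0 + w, H, 1, omega0, w), H / 2,
                 tolerance = 1e-12)
  }
})

test_that("binomial multiplet weights match the closed forms", {
  expect_equal(multiplet_heights(1), 1)
  expect_equal(multiplet_heights(2), c(0.5, 0.5))
  expect_equal(multiplet_heights(3), c(0.25, 0.5, 0.25))
  expect_equal(multiplet_heights(5), c(1, 4, 6, 4, 1) / 16)
  expect_equal(multiplet_heights(7), choose(6, 0:6) / 64)
  for (m in 1:7) expect_equal(sum(multiplet_heights(m)), 1)
  expect_error(multiplet_heights(0), "1..7")
  expect_error(multiplet_heights(8), "1..7")
})

test_that("multiplets render as equidistant scaled components", {
  grid <- seq(-100, 100, by = 0.05)
  # singlet: one peak of height h_i * h_m * h_s
  sp1 <- multiplet_spec(1, 0, 0, 1.5, 2, 3, 0, 10)
  v1 <- render_multiplet(grid, sp1, w_s = 0.5, h_s = 1.5)
  expect_equal(max(v1), 2 * 3 * 1.5, tolerance = 1e-6)
  expect_equal(grid[which.max(v1)], 10, tolerance = 0.05)

  # doublet split by j1 = 10 Hz: two equal peaks at +/- 5 Hz around center
  sp2 <- multiplet_spec(2, 10, 0, 1.5, 1, 1, 0, 0)
  v2 <- render_multiplet(grid, sp2, w_s = 0.5, h_s = 1)
  peaks <- grid[which(diff(sign(diff(v2))) == -2) + 1]
  expect_equal(sort(peaks), c(-5, 5), tolerance = 0.1)

  # secondary split preserves the integrated area
  sp3 <- multiplet_spec(3, 8, 2, 1.5, 2, 1, 0.3, 0, secondary_split = FALSE)
  sp3s <- multiplet_spec(3, 8, 2, 1.5, 2, 1, 0.3, 0, secondary_split = TRUE)
  a <- sum(render_multiplet(grid, sp3, 0.5, 1)) * 0.05
  as <- sum(render_multiplet(grid, sp3s, 0.5, 1)) * 0.05
  expect_equal(as, a, tolerance = 1e-6)
})

test_that("spectrum sampling is reproducible and respects its ranges", {
  cfg <- sampling_config(n_points = 256L, delta_f = 0.3406)
  set.seed(61); a <- sample_spectrum(cfg)
  set.seed(61); b <- sample_spectrum(cfg)
  expect_identical(a$values, b$values)
  expect_identical(a$record, b$record)

  set.seed(62)
  for (i in 1:200) {
    s <- sample_spectrum(cfg)
    rec <- s$record
    M <- attr(rec, "M")
    expect_true(M >= 2 && M <= 5)
    expect_true(all(rec$m >= 1 & rec$m <= 7))
    expect_true(all(rec$j1 >= 0 & rec$j1 <= 15))
    expect_true(all(rec$j2 >= 0 & rec$j2 <= 15))
    expect_true(all(rec$w_m >= 1 & rec$w_m <= 2))
    expect_true(all(rec$h_i >= 1 & rec$h_i <= 3))
    expect_true(all(rec$h_m >= 0.5 & rec$h_m <= 4))
    expect_true(all(rec$gamma >= 0 & rec$gamma <= 1))
    expect_true(attr(rec, "w_s") >= 0.2 && attr(rec, "w_s") <= 1)
    expect_true(attr(rec, "h_s") >= 0.5 && attr(rec, "h_s") <= 2)
    expect_true(all(is.finite(s$values)))
  }
})

test_that("hybrid examples reduce to the clean spectrum for impulse kernels", {
  cfg <- sampling_config(n_points = 256L, delta_f = 0.5, noise_max = 0)
  lib <- impulse_library(11L, 0.5, m = 4L)
  set.seed(63)
  s <- sample_spectrum(cfg)
  ex <- make_training_example(s$values, lib, noise_max = 0)
  expect_identical(ex$s_inp, ex$s_trg)
  expect_equal(ex$noise_sd, 0)
})

test_that("hybrid convolution matches the direct-sum oracle and seeds repeat", {
  pre <- smoke_fixture()
  set.seed(64)
  s <- sample_spectrum(pre$config)
  ex <- make_training_example(s$values, pre$library, noise_max = 0)
  expect_equal(ex$s_inp, conv_oracle(s$values, ex$r_trg), tolerance = 1e-12)

  set.seed(65); e1 <- make_training_example(s$values, pre$library, 0.02)
  set.seed(65); e2 <- make_training_example(s$values, pre$library, 0.02)
  expect_identical(e1$s_inp, e2$s_inp)
  expect_identical(e1$response_index, e2$response_index)
})

test_that("unit-sum kernels conserve the spectrum integral for interior peaks", {
  pre <- smoke_fixture()
  cfg <- sampling_config(n_points = 1024L, delta_f = pre$config$delta_f,
                         omega0_range = 20)  # keep peaks well inside the grid
  set.seed(66)
  for (i in 1:5) {
    s <- sample_spectrum(cfg)
    ex <- make_training_example(s$values, pre$library, noise_max = 0)
    expect_equal(sum(ex$s_inp), sum(ex$s_trg),
                 tolerance = 1e-6 * abs(sum(ex$s_trg)))
  }
})

test_that("batch generation never reuses RNG draws between batches", {
  pre <- smoke_fixture()
  set.seed(67)
  b1 <- generate_batch(pre$config, pre$library, 4L)
  b2 <- generate_batch(pre$config, pre$library, 4L)
  expect_gt(max(abs(b1$s_trg - b2$s_trg)), 0)
})
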