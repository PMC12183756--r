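test_that("the default schedule reproduces the published ramp", {
  sch <- training_schedule()
  expect_equal(schedule_total(sch), 40e6)
  expect_equal(sch$batch_size, c(64L, 512L, 512L))
  expect_equal(sch$learning_rate, c(1e-3, 1e-3, 5e-4))
  expect_error(training_schedule(n_spectra = 100, batch_size = 64L,
                                 learning_rate = 1e-3), "divisible")
  expect_error(training_schedule(n_spectra = 128, batch_size = 64L,
                                 learning_rate = 0), "> 0")
})

test_that("the three-term loss matches a scalar-by-scalar oracle", {
  # hand-built K = 1 batch of 8 points with a unit impulse response
  s_trg <- c(0, 1, 2, 1, 0, 0.5, 0.25, 0)
  s_out <- c(0.1, 0.9, 2.2, 1, 0, 0.4, 0.25, -0.1)
  r_trg <- c(0, 1, 0)
  r_out <- c(0.05, 0.9, 0.02)
  s_inp <- c(0, 1.1, 2, 1, 0.05, 0.5, 0.2, 0)

  lb <- shim_loss(s_trg, s_inp, s_out, r_trg, r_out)

  # independent elementwise computation
  rec <- mean((s_trg - s_out)^2)
  dis <- mean((r_trg - r_out)^2)
  reconv <- numeric(8)
  for (i in 1:8) {
    for (t in 1:3) {
      src <- i - (t - 2)
      if (src >= 1 && src <= 8) reconv[i] <- reconv[i] + r_out[t] * s_out[src]
    }
  }
  con <- mean((s_inp - reconv)^2)
  expect_equal(lb$reconstruction, rec, tolerance = 1e-12)
  expect_equal(lb$distortion, dis, tolerance = 1e-12)
  expect_equal(lb$consistency, con, tolerance = 1e-12)
  expect_equal(lb$total, rec + dis + con, tolerance = 1e-12)
})

test_that("the loss vanishes at the perfect solution and ignores duplication", {
  set.seed(81)
  L <- 32L; n <- 5L
  s_trg <- matrix(stats::rnorm(L), L, 1)
  r_trg <- matrix(c(0.1, 0.2, 0.4, 0.2, 0.1), n, 1)
  s_inp <- conv_same_batch(s_trg, r_trg)  # noise-free hybrid
  lb <- shim_loss(s_trg, s_inp, s_trg, r_trg, r_trg)
  expect_equal(lb$total, 0, tolerance = 1e-12)

  # duplicating batch members leaves the mean-based loss unchanged
  s_out <- s_trg + 0.1
  r_out <- r_trg + 0.05
  l1 <- shim_loss(s_trg, s_inp, s_out, r_trg, r_out)
  l2 <- shim_loss(cbind(s_trg, s_trg), cbind(s_inp, s_inp),
                  cbind(s_out, s_out), cbind(r_trg, r_trg),
                  cbind(r_out, r_out))
  expect_equal(l2$total, l1$total, tolerance = 1e-12)

  # the C++ training-path loss agrees with the R implementation
  cfg <- shim_model_config(channels = 4L, kernel = 3L, depth = 2L,
                           aux_hidden = 4L, n_response = n)
  st <- shim_model_init(cfg, seed = 10)
  fw <- model_forward(s_inp, st)
  lb_r <- shim_loss(s_trg, s_inp, fw$s_out, r_trg, fw$r_out)
  lb_c <- nmrshim:::nn_loss_grad(st$params, unclass(cfg), s_inp, s_trg,
                                 r_trg, want_grad = FALSE)
  expect_equal(lb_c$total, lb_r$total, tolerance = 1e-12)
})

test_that("one optimizer step moves parameters in every layer", {
  pre <- smoke_fixture()
  cfg <- pre$model_config
  st <- shim_model_init(cfg, seed = 11)
  sch <- training_schedule(n_spectra = 64, batch_size = 64L,
                           learning_rate = 1e-3)
  tr <- train_model(st, pre$library, pre$config, sch, seed = 12)
  info <- param_info(cfg)
  off <- cumsum(c(0, info$size))
  for (i in seq_len(nrow(info))) {
    delta <- tr$params[(off[i] + 1):off[i + 1]] -
      st$params[(off[i] + 1):off[i + 1]]
    expect_gt(max(abs(delta)), 0, label = info$name[i])
  }
  expect_identical(nrow(attr(tr, "loss_history")), 1L)
})

test_that("training is reproducible under a fixed seed", {
  pre <- smoke_fixture()
  st <- shim_model_init(pre$model_config, seed = 13)
  sch <- training_schedule(n_spectra = 192, batch_size = 64L,
                           learning_rate = 1e-3)
  t1 <- train_model(st, pre$library, pre$config, sch, seed = 14)
  t2 <- train_model(st, pre$library, pre$config, sch, seed = 14)
  expect_identical(t1$params, t2$params)
  expect_identical(attr(t1, "loss_history")$total,
                   attr(t2, "loss_history")$total)
})

test_that("smoke training reduces the loss over the run", {
  tr <- smoke_trained(1)
  h <- attr(tr, "loss_history")$total
  n <- length(h)
  expect_lt(mean(h[(n - 99):n]), mean(h[1:100]))
})

test_that("evaluation reports sensible metrics for trivial baselines", {
  pre <- smoke_fixture()
  st <- shim_model_init(pre$model_config, seed = 15)

  # identity library, noise off: the baseline error is exactly zero
  cfg0 <- pre$config
  cfg0$noise_max <- 0
  lib0 <- impulse_library(pre$plan$n_response, pre$config$delta_f, m = 3L)
  ev0 <- evaluate_model(st, 16L, lib0, cfg0, seed = 16)
  expect_equal(ev0$baseline_mse, 0, tolerance = 1e-24)

  # untrained model: corrected error is of the baseline's order, not better
  ev <- evaluate_model(st, 32L, pre$library, pre$config, seed = 17)
  expect_gt(ev$corrected_mse, 0.5 * ev$baseline_mse)
})
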