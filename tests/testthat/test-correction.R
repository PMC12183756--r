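test_that("correction preserves the grid and the tallest-peak height", {
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  set.seed(91)
  s <- sample_spectrum(pre$config)
  ex <- make_training_example(s$values, pre$library, noise_max = 0.01)
  inp <- spectrum1d(s$grid[1], pre$config$delta_f, ex$s_inp)

  res <- correct(inp, tr)
  expect_s3_class(res, "correction_result")
  expect_identical(length(res$corrected$values), length(inp$values))
  expect_equal(res$corrected$freq_start, inp$freq_start)
  expect_equal(res$corrected$freq_step, inp$freq_step)
  expect_true(all(is.finite(res$corrected$values)))
  expect_true(all(res$attention >= 0))
  expect_equal(max(res$corrected$values), max(inp$values), tolerance = 0.02)

  # determinism
  res2 <- correct(inp, tr)
  expect_identical(res2$corrected$values, res$corrected$values)
})

test_that("correcting a simulated mis-shimmed spectrum moves it toward the clean one", {
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  set.seed(92)
  s <- sample_spectrum(pre$config)
  ex <- make_training_example(s$values, pre$library, noise_max = 0.01)
  clean <- s$values
  inp <- spectrum1d(s$grid[1], pre$config$delta_f, ex$s_inp)
  res <- correct(inp, tr)
  mse_corr <- mean((res$corrected$values - clean)^2)
  mse_dist <- mean((ex$s_inp - clean)^2)
  expect_lt(mse_corr, mse_dist)
})

test_that("inputs on a foreign grid are resampled there and back", {
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  set.seed(93)
  cfg_wide <- sampling_config(n_points = 512L, delta_f = pre$config$delta_f)
  s <- sample_spectrum(cfg_wide)
  fine <- resample(spectrum1d(s$grid[1], cfg_wide$delta_f, s$values),
                   cfg_wide$delta_f / 2)
  res <- correct(fine, tr)
  expect_identical(length(res$corrected$values), length(fine$values))
  expect_equal(res$corrected$freq_step, fine$freq_step)
})

test_that("degenerate inputs fail loudly", {
  tr <- smoke_trained(1)
  neg <- spectrum1d(0, 0.3406, rep(-1, 128))
  expect_error(correct(neg, tr), "no positive peak")

  tiny <- lorentzian_spectrum(n = 130L, delta_f = 0.05, w = 0.5)
  # 130 points at 0.05 Hz span 6.5 Hz -> ~19 points at the model step
  expect_error(correct(tiny, tr), "64")

  untrained <- shim_model_init(smoke_fixture()$model_config, seed = 1)
  expect_error(correct(lorentzian_spectrum(), untrained), "delta_f")
})

test_that("batch correction isolates per-file failures", {
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  dir_in <- withr::local_tempdir()
  dir_out <- withr::local_tempdir()
  set.seed(94)
  paths <- character(3)
  for (i in 1:2) {
    s <- sample_spectrum(pre$config)
    ex <- make_training_example(s$values, pre$library, 0.005)
    paths[i] <- file.path(dir_in, sprintf("s%d.txt", i))
    write_spectrum_text(spectrum1d(s$grid[1], pre$config$delta_f, ex$s_inp),
                        paths[i])
  }
  paths[3] <- file.path(dir_in, "corrupt.txt")
  writeLines(c("0 1", "0.3406 broken"), paths[3])

  report <- batch_correct(paths, tr, dir_out)
  expect_identical(nrow(report), 3L)
  expect_identical(sum(report$ok), 2L)
  expect_match(report$error[3], "line 2")
  expect_length(list.files(dir_out), 2L)

  empty <- batch_correct(character(0), tr, dir_out)
  expect_identical(nrow(empty), 0L)
})

test_that("attention percentages partition to 100 over covering regions", {
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  set.seed(95)
  s <- sample_spectrum(pre$config)
  ex <- make_training_example(s$values, pre$library, 0.005)
  inp <- spectrum1d(s$grid[1], pre$config$delta_f, ex$s_inp)
  res <- correct(inp, tr)
  span <- range(freq_axis(inp))

  whole <- attention_report(res, list(span))
  expect_equal(whole$weight_pct, 100, tolerance = 0.1)

  mid <- mean(span)
  halves <- attention_report(res, rbind(c(span[1], mid - 1e-9),
                                        c(mid, span[2])))
  expect_equal(sum(halves$weight_pct), 100, tolerance = 0.1)

  expect_error(attention_report(res, list(c(span[1] - 10, span[2]))),
               "within the spectrum span")
})

test_that("narrow singlets attract more attention than broad ones", {
  # qualitative property of the trained attention: across several random
  # placements, the narrow singlet's region weight usually dominates
  tr <- smoke_trained(1)
  pre <- smoke_fixture()
  delta_f <- pre$config$delta_f
  n <- 256L
  start <- -(n - 1) / 2 * delta_f
  freqs <- start + (seq_len(n) - 1L) * delta_f
  wins <- 0L
  set.seed(96)
  for (i in 1:5) {
    pos <- sample(c(-1, 1), 1)
    narrow_c <- pos * stats::runif(1, 15, 25)
    broad_c <- -pos * stats::runif(1, 15, 25)
    vals <- lg_peak(freqs, 10, 0, narrow_c, 0.25) +
      lg_peak(freqs, 10, 0, broad_c, 2.5)
    res <- correct(spectrum1d(start, delta_f, vals), tr)
    rep_ <- attention_report(res, rbind(c(narrow_c - 8, narrow_c + 8),
                                        c(broad_c - 8, broad_c + 8)))
    if (rep_$weight_pct[1] > rep_$weight_pct[2]) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})
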