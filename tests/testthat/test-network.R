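test_that("parameter counts decompose as the architecture dictates", {
  cfg <- shim_model_config()
  st <- shim_model_init(cfg, seed = 1)
  # encoder: (64*7 + 64) + 3 * (64*64*7 + 64)
  expect_identical(count_parameters(st, "encoder"), 86720L)
  expect_identical(count_parameters(st, "attention"), 64L)
  # decoder mirrors the encoder with doubled input channels
  expect_identical(count_parameters(st, "decoder"),
                   (64L * 128L * 7L + 64L) + 2L * (64L * 64L * 7L + 64L) +
                     (64L * 7L + 1L))
  expect_identical(count_parameters(st, "inference"), 202113L)
  expect_identical(count_parameters(st),
                   202113L + count_parameters(st, "aux"))
  # initialization is reproducible under the seed
  st2 <- shim_model_init(cfg, seed = 1)
  expect_identical(st$params, st2$params)
})

test_that("encoder has the configured receptive field and is shift-equivariant", {
  cfg <- shim_model_config()
  st <- shim_model_init(cfg, seed = 2)
  expect_equal(unname(receptive_fields(cfg)), c(25L, 49L))

  set.seed(71)
  L <- 512L
  x <- stats::rnorm(L)
  lat0 <- encode(x, st)
  x2 <- x; x2[256] <- x2[256] + 1
  lat1 <- encode(x2, st)
  changed <- which(colSums(abs(lat1[, , 1] - lat0[, , 1])) > 0)
  expect_identical(length(changed), 25L)
  expect_identical(range(changed), c(256L - 12L, 256L + 12L))

  # translation equivariance away from the edges
  shift <- 10L
  xs <- c(numeric(shift), x[1:(L - shift)])
  lats <- encode(xs, st)
  interior <- 60:450
  expect_equal(lats[, interior + shift, 1], lat0[, interior, 1],
               tolerance = 1e-12)

  # all-zero input gives constant latent rows away from edges
  latz <- encode(numeric(128L), st)[, , 1]
  expect_equal(latz[, 30], latz[, 60], tolerance = 1e-12)
})

test_that("attention weights form a probability vector built from the query", {
  cfg <- shim_model_config(channels = 8L, aux_hidden = 8L, n_response = 9L)
  st <- shim_model_init(cfg, seed = 3)
  set.seed(72)
  x <- stats::rnorm(256)
  lat <- encode(x, st)
  att <- attend(lat, st)
  expect_equal(sum(att$weights), 1, tolerance = 1e-6)
  expect_true(all(att$weights >= 0))
  expect_length(att$global, 8L)

  # identical latent rows give uniform weights
  H <- matrix(rep(stats::rnorm(8), 100), 8, 100)
  att_u <- attend(H, st)
  expect_equal(att_u$weights, rep(1 / 100, 100), tolerance = 1e-12)

  # the R-level pooling agrees with the fused forward pass
  fw <- model_forward(x, st)
  expect_equal(att$weights, fw$weights, tolerance = 1e-12)
  expect_equal(att$global, drop(fw$global), tolerance = 1e-12)
})

test_that("decoder output is length-preserving and locally bounded", {
  cfg <- shim_model_config(channels = 8L, aux_hidden = 8L, n_response = 9L)
  st <- shim_model_init(cfg, seed = 4)
  fg <- rep(0.3, 8)
  for (L in c(64L, 2048L, 5000L)) {
    out <- model_forward(stats::rnorm(L), st, frozen_global = fg)
    expect_length(out$s_out, L)
    expect_true(all(is.finite(out$s_out)))
  }

  # with the global vector frozen, one input point touches <= 49 outputs
  set.seed(73)
  x <- stats::rnorm(400)
  o0 <- model_forward(x, st, frozen_global = fg)
  x2 <- x; x2[200] <- x2[200] + 1
  o1 <- model_forward(x2, st, frozen_global = fg)
  expect_lte(sum(abs(o1$s_out - o0$s_out) > 0), 49L)

  # module-level decode agrees with the fused path
  lat <- encode(x, st)
  dec <- decode(lat, fg, st)
  expect_equal(dec, o0$s_out, tolerance = 1e-12)
})

test_that("the auxiliary decoder is a two-layer map with the stated closed form", {
  cfg <- shim_model_config(channels = 8L, aux_hidden = 16L, n_response = 11L)
  st <- shim_model_init(cfg, seed = 5)
  g <- stats::rnorm(8)
  r1 <- decode_response(g, st)
  r2 <- decode_response(g, st)
  expect_length(r1, 11L)
  expect_identical(r1, r2)

  # zero input: second layer's image of relu(first bias)
  info <- param_info(cfg)
  off <- cumsum(c(0, info$size))
  slot <- function(nm) {
    i <- which(info$name == nm)
    array(st$params[(off[i] + 1):off[i + 1]], c(info$rows[i], info$cols[i]))
  }
  expected <- slot("aux_w2") %*% pmax(slot("aux_b1"), 0) + slot("aux_b2")
  expect_equal(decode_response(numeric(8), st), drop(expected),
               tolerance = 1e-12)
})

test_that("batched forward equals independent per-spectrum forwards", {
  cfg <- shim_model_config(channels = 8L, aux_hidden = 8L, n_response = 9L)
  st <- shim_model_init(cfg, seed = 6)
  set.seed(74)
  X <- matrix(stats::rnorm(256 * 5), 256, 5)
  joint <- model_forward(X, st)
  for (i in 1:5) {
    single <- model_forward(X[, i], st)
    expect_equal(joint$s_out[, i], single$s_out, tolerance = 1e-6)
    expect_equal(joint$r_out[, i], single$r_out, tolerance = 1e-6)
    expect_equal(joint$weights[, i], single$weights, tolerance = 1e-6)
  }
})

test_that("inputs shorter than the receptive field are rejected", {
  cfg <- shim_model_config()
  st <- shim_model_init(cfg, seed = 7)
  expect_error(model_forward(stats::rnorm(32), st), "receptive field")
})

test_that("the analytic gradient matches finite differences", {
  cfg <- shim_model_config(channels = 3L, kernel = 3L, depth = 2L,
                           aux_hidden = 4L, n_response = 5L)
  st <- shim_model_init(cfg, seed = 8)
  set.seed(75)
  L <- 20L; K <- 2L
  S_inp <- matrix(stats::rnorm(L * K), L, K)
  S_trg <- matrix(stats::rnorm(L * K), L, K)
  R_trg <- matrix(stats::rnorm(5 * K), 5, K)
  cfg_l <- unclass(cfg)
  lg <- nmrshim:::nn_loss_grad(st$params, cfg_l, S_inp, S_trg, R_trg)
  f <- function(p) {
    nmrshim:::nn_loss_grad(p, cfg_l, S_inp, S_trg, R_trg,
                           want_grad = FALSE)$total
  }
  eps <- 1e-6
  idx <- sort(sample(length(st$params), 60L))
  num <- vapply(idx, function(i) {
    p1 <- st$params; p1[i] <- p1[i] + eps
    p2 <- st$params; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
  expect_equal(lg$grad[idx], num, tolerance = 1e-5)
})

test_that("checkpoints round-trip the full model state", {
  cfg <- shim_model_config(channels = 4L, aux_hidden = 4L, n_response = 5L)
  st <- shim_model_init(cfg, seed = 9)
  st$meta$delta_f <- 0.34
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(st, path)
  st2 <- load_checkpoint(path)
  expect_identical(st2$params, st$params)
  expect_identical(st2$meta$delta_f, 0.34)
  expect_identical(unclass(st2$config), unclass(cfg))
})
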