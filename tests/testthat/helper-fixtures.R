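# Shared fixtures. Heavyweight artifacts (the smoke preset's response
# library and smoke-trained models) are built lazily once per test run and
# cached, since several test files exercise them from different angles.

.fixture_env <- new.env(parent = emptyenv())

# A smooth single-Lorentzian test spectrum on a grid that contains omega0
# exactly, so the sampled maximum equals `height`.
lorentzian_spectrum <- function(n = 512L, delta_f = 0.5, w = 2, height = 10,
                                omega0 = 0) {
  start <- omega0 - (n %/% 2L) * delta_f
  freqs <- start + (seq_len(n) - 1L) * delta_f
  spectrum1d(start, delta_f, height * w^2 / (w^2 + (freqs - omega0)^2))
}

# Brute-force O(L * N) centered same-convolution, the oracle the fast path
# is checked against.
conv_oracle <- function(x, r) {
  L <- length(x)
  n <- length(r)
  ctr <- (n - 1L) %/% 2L
  y <- numeric(L)
  for (i in seq_len(L)) {
    for (t in seq_len(n)) {
      src <- i - (t - 1L - ctr)
      if (src >= 1L && src <= L) y[i] <- y[i] + r[t] * x[src]
    }
  }
  y
}

smoke_fixture <- function() {
  if (is.null(.fixture_env$preset)) {
    .fixture_env$preset <- smoke_preset()
  }
  .fixture_env$preset
}

# One smoke training run per seed, cached across test files.
smoke_trained <- function(seed) {
  key <- paste0("model_", seed)
  if (is.null(.fixture_env[[key]])) {
    pre <- smoke_fixture()
    st <- shim_model_init(pre$model_config, seed = seed)
    .fixture_env[[key]] <- train_model(st, pre$library, pre$config,
                                       pre$schedule, seed = seed)
  }
  .fixture_env[[key]]
}
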