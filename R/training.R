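#' Training schedule
#'
#' Ordered phases of online training; within each phase the batch size and
#' learning rate are constant. The default schedule ramps the batch size up
#' while stepping the learning rate down: 1.6 M spectra at batch 64 and rate
#' 1e-3, then 25.6 M at batch 512 and 1e-3, then 12.8 M at batch 512 and
#' 5e-4 - 40 M generated spectra in total.
#'
#' @param n_spectra Numeric vector: spectra per phase (each divisible by the
#'   phase's batch size).
#' @param batch_size Integer vector of batch sizes `K`.
#' @param learning_rate Numeric vector of positive Adam learning rates.
#' @return An object of class `training_schedule` (a data.frame).
#' @export
training_schedule <- function(n_spectra = c(1.6e6, 25.6e6, 12.8e6),
                              batch_size = c(64L, 512L, 512L),
                              learning_rate = c(1e-3, 1e-3, 5e-4)) {
  if (length(n_spectra) != length(batch_size) ||
      length(n_spectra) != length(learning_rate)) {
    stop("schedule columns must have equal length", call. = FALSE)
  }
  if (any(learning_rate <= 0)) {
    stop("learning rates must be > 0", call. = FALSE)
  }
  if (any(n_spectra %% batch_size != 0)) {
    stop("`n_spectra` must be divisible by `batch_size` in every phase",
         call. = FALSE)
  }
  structure(
    data.frame(n_spectra = as.numeric(n_spectra),
               batch_size = as.integer(batch_size),
               learning_rate = as.numeric(learning_rate)),
    class = c("training_schedule", "data.frame")
  )
}

#' Total number of spectra a schedule generates
#'
#' @param schedule A [training_schedule].
#' @return Numeric total.
#' @export
schedule_total <- function(schedule) {
  stopifnot(inherits(schedule, "training_schedule"))
  sum(schedule$n_spectra)
}

#' Three-term training loss
#'
#' `L = 1/K * (|S_trg - S_out|^2 + |R_trg - R_out|^2 +
#'  |S_inp - S_out * R_out|^2)`, where `*` is the centered same-mode
#' convolution and each `|.|^2` is the mean of squared element differences
#' over its vector. The first (reconstruction) term drives the corrected
#' spectra toward the clean targets; the second (distortion) term makes the
#' auxiliary decoder recover the applied response function; the third
#' (consistency) term requires that re-distorting the corrected spectrum with
#' the estimated response reproduces the input.
#'
#' @param s_trg,s_inp,s_out L x K matrices (clean targets, hybrid inputs,
#'   model outputs).
#' @param r_trg,r_out N x K matrices (true and estimated response kernels).
#' @return A list of class `loss_breakdown` with fields `reconstruction`,
#'   `distortion`, `consistency`, `total`.
#' @export
shim_loss <- function(s_trg, s_inp, s_out, r_trg, r_out) {
  s_trg <- as.matrix(s_trg); s_inp <- as.matrix(s_inp)
  s_out <- as.matrix(s_out)
  r_trg <- as.matrix(r_trg); r_out <- as.matrix(r_out)
  if (!all(dim(s_trg) == dim(s_inp)) || !all(dim(s_trg) == dim(s_out))) {
    stop("spectrum batches must share one L x K shape", call. = FALSE)
  }
  if (!all(dim(r_trg) == dim(r_out)) || ncol(r_trg) != ncol(s_trg)) {
    stop("response batches must be N x K", call. = FALSE)
  }
  k <- ncol(s_trg)
  reconv <- conv_same_batch(s_out, r_out)
  breakdown <- list(
    reconstruction = sum(colMeans((s_trg - s_out)^2)) / k,
    distortion = sum(colMeans((r_trg - r_out)^2)) / k,
    consistency = sum(colMeans((s_inp - reconv)^2)) / k
  )
  breakdown$total <- breakdown$reconstruction + breakdown$distortion +
    breakdown$consistency
  structure(breakdown, class = "loss_breakdown")
}

## One Adam step; `opt` carries the moment estimates and step counter.
## Gradients are clipped to a global L2 norm of `clip` before the moment
## updates: the first few batches of a fresh model produce gradients orders
## of magnitude above steady state, and unclipped they poison the
## second-moment estimates for a large part of a short run.
.adam_step <- function(params, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(grad^2))
  if (is.finite(gnorm) && gnorm > clip) grad <- grad * (clip / gnorm)
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * grad
  opt$v <- beta2 * opt$v + (1 - beta2) * grad^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(params = params - lr * mhat / (sqrt(vhat) + eps), opt = opt)
}

#' Train the correction network online
#'
#' Runs the hybrid online training loop: for every batch a fresh set of clean
#' synthetic spectra is drawn, convolved with randomly chosen library
#' kernels and noised ([generate_batch()]); the batch is pushed through the
#' network; the three-term loss ([shim_loss()]) is minimized with Adam
#' (moments 0.9/0.999, epsilon 1e-8) at the phase's learning rate. No batch
#' is ever reused. No dropout or weight decay is applied. Checkpoints are
#' written every `checkpoint_every` batches and at each phase end when
#' `checkpoint_path` is given. Fully reproducible under `seed`.
#'
#' @param state A [shim_model] (freshly initialized or resumed).
#' @param library A non-empty [response_library]; its kernel length must
#'   equal the model's `n_response` and its `delta_f` the sampling config's.
#' @param config A [sampling_config] describing the synthetic spectra.
#' @param schedule A [training_schedule].
#' @param seed Integer seed governing all batch generation.
#' @param precision `"single"` (default) or `"double"`: floating-point
#'   precision of the gradient computation. Single precision is the standard
#'   choice for stochastic gradient training and roughly doubles throughput;
#'   the optimizer state and parameters are kept in double either way.
#' @param checkpoint_path Optional path for periodic checkpoints.
#' @param checkpoint_every Batches between checkpoints (default 1000).
#' @param verbose Print a progress line every 100 batches.
#' @return The trained [shim_model]; the per-batch loss history (data.frame
#'   with the three terms and the total) is attached as
#'   `attr(, "loss_history")`, and the number of consumed examples as
#'   `$meta$trained_spectra`.
#' @export
train_model <- function(state, library, config, schedule, seed = 1L,
                        precision = c("single", "double"),
                        checkpoint_path = NULL, checkpoint_every = 1000L,
                        verbose = FALSE) {
  precision <- match.arg(precision)
  stopifnot(inherits(state, "shim_model"),
            inherits(library, "response_library"),
            inherits(config, "sampling_config"),
            inherits(schedule, "training_schedule"))
  if (library_size(library) < 1L) stop("response library is empty", call. = FALSE)
  if (nrow(library$values) != state$config$n_response) {
    stop(sprintf("library kernel length %d != model n_response %d",
                 nrow(library$values), state$config$n_response), call. = FALSE)
  }
  if (abs(library$delta_f - config$delta_f) > 1e-9 * config$delta_f) {
    stop("library and sampling config disagree on delta_f", call. = FALSE)
  }

  params <- state$params
  opt <- list(m = numeric(length(params)), v = numeric(length(params)),
              t = 0L)
  history <- vector("list", sum(schedule$n_spectra / schedule$batch_size))
  batch_no <- 0L
  cfg_list <- unclass(state$config)

  .with_seed(seed, {
    for (ph in seq_len(nrow(schedule))) {
      k <- schedule$batch_size[ph]
      lr <- schedule$learning_rate[ph]
      n_batches <- schedule$n_spectra[ph] / k
      for (bi in seq_len(n_batches)) {
        batch <- generate_batch(config, library, k)
        res <- nn_loss_grad(params, cfg_list, batch$s_inp, batch$s_trg,
                            batch$r_trg, precision = precision)
        if (!is.finite(res$total)) {
          if (!is.null(checkpoint_path)) {
            diag_state <- state
            diag_state$params <- params
            save_checkpoint(diag_state,
                            paste0(checkpoint_path, ".diverged"))
          }
          stop(sprintf(
            "non-finite loss at phase %d batch %d; training aborted", ph, bi),
            call. = FALSE)
        }
        stepped <- .adam_step(params, res$grad, opt, lr)
        params <- stepped$params
        opt <- stepped$opt
        batch_no <- batch_no + 1L
        history[[batch_no]] <- c(res$reconstruction, res$distortion,
                                 res$consistency, res$total)
        if (verbose && batch_no %% 100L == 0L) {
          message(sprintf("phase %d batch %d/%d loss %.5f", ph, bi,
                          n_batches, res$total))
        }
        if (!is.null(checkpoint_path) &&
            batch_no %% checkpoint_every == 0L) {
          ck <- state; ck$params <- params
          save_checkpoint(ck, checkpoint_path)
        }
      }
      if (!is.null(checkpoint_path)) {
        ck <- state; ck$params <- params
        save_checkpoint(ck, checkpoint_path)
      }
    }
  })

  state$params <- params
  state$meta$delta_f <- config$delta_f
  state$meta$target_height <- 16
  state$meta$library_fingerprint <- sum(library$values) +
    998244353 * library_size(library)
  state$meta$trained_spectra <- state$meta$trained_spectra +
    schedule_total(schedule)
  hist_mat <- do.call(rbind, history[seq_len(batch_no)])
  attr(state, "loss_history") <- data.frame(
    batch = seq_len(batch_no), reconstruction = hist_mat[, 1],
    distortion = hist_mat[, 2], consistency = hist_mat[, 3],
    total = hist_mat[, 4])
  state
}

#' Evaluate a model on freshly generated examples
#'
#' Generates `n_eval` hybrid examples and reports the mean squared error of
#' the corrected spectra against the clean targets, the baseline mean
#' squared error of the uncorrected inputs against the same targets, and the
#' mean Pearson correlation between estimated and true response kernels.
#'
#' @param state A [shim_model].
#' @param n_eval Number of evaluation examples.
#' @param library A [response_library].
#' @param config A [sampling_config].
#' @param seed Integer seed for the evaluation draws.
#' @return A list with `corrected_mse`, `baseline_mse`,
#'   `response_correlation`.
#' @export
evaluate_model <- function(state, n_eval, library, config, seed = 1L) {
  stopifnot(inherits(state, "shim_model"))
  batch <- .with_seed(seed, generate_batch(config, library, n_eval))
  out <- nn_forward(state$params, unclass(state$config), batch$s_inp)
  corr <- vapply(seq_len(n_eval), function(i) {
    if (stats::sd(out$r_out[, i]) == 0 || stats::sd(batch$r_trg[, i]) == 0) {
      return(0)
    }
    stats::cor(out$r_out[, i], batch$r_trg[, i])
  }, numeric(1))
  list(
    corrected_mse = mean((out$s_out - batch$s_trg)^2),
    baseline_mse = mean((batch$s_inp - batch$s_trg)^2),
    response_correlation = mean(corr)
  )
}

#' Desk-scale smoke training preset
#'
#' A complete, self-consistent miniature of the full training study, sized
#' for a few minutes on a single CPU core: a 16 x 16 shim grid spanning
#' +/-37.5 simulator units (256 response kernels), 256-point synthetic
#' spectra at the default 0.3406 Hz step, a 12 Hz / 37-point response window,
#' a 32-channel model, and a single-phase schedule of ~50,000 online spectra
#' at batch 64 and learning rate 1e-3. All other sampling ranges keep their
#' full-scale values.
#'
#' @return A list with `plan` ([resolution_plan]), `model` ([field_model]),
#'   `grid` ([calibration_grid]), `library` (ground-truth
#'   [response_library]), `config` ([sampling_config]), `model_config`
#'   ([shim_model_config]), `schedule` ([training_schedule]).
#' @export
smoke_preset <- function() {
  delta_f <- 0.3406
  plan <- resolution_plan(delta_f, W = 12, fwhm_min = 0.4, fwhm_max = 4)
  fm <- field_model()
  grid <- calibration_grid(-37.5, 37.5, 5, -37.5, 37.5, 5)
  settings <- grid_settings(grid)
  truth <- matrix(0, plan$n_response, nrow(settings))
  for (i in seq_len(nrow(settings))) {
    truth[, i] <- simulate_response(
      shim_setting(settings$z1[i], settings$z2[i]), fm, delta_f,
      plan$n_response)$values
  }
  library <- response_library(truth, delta_f, settings = settings,
                              grid_shape = c(grid$n1, grid$n2))
  config <- sampling_config(n_points = 256L, delta_f = delta_f)
  model_config <- shim_model_config(channels = 32L, aux_hidden = 32L,
                                    n_response = plan$n_response)
  # 782 batches of 64 = 50,048 spectra (the nearest batch multiple of 50,000)
  schedule <- training_schedule(n_spectra = 50048, batch_size = 64L,
                                learning_rate = 1e-3)
  list(plan = plan, model = fm, grid = grid, library = library,
       config = config, model_config = model_config, schedule = schedule)
}
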