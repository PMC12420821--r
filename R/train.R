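#' Training configuration
#'
#' Collects every knob of a training run in one validated list. Defaults
#' reproduce the package's reference study conditions: a 4-30-3 network on
#' the Yin-Yang task with span `2 tau_s`, time-invariant separation loss
#' with `delta_t = 0.2 tau_s`, Adam with separate learning rates for
#' weights and raw delay parameters, 5000/1000/1000 train/validation/test
#' samples regenerated per seed, and 300 epochs with no early stopping
#' (the best-validation checkpoint is reported alongside the final one).
#'
#' @param hidden Hidden layer size (or vector of hidden sizes for deeper
#'   stacks).
#' @param delay_kind `"none"`, `"axonal"`, `"dendritic"` or `"synaptic"`.
#' @param lambda Maximum delay \eqn{\lambda} (units of `tau_s`).
#' @param span,t0 Input encoding, see [encode_spikes()].
#' @param tau_ratio Membrane/synaptic time-constant ratio (1 or 2).
#' @param delta_t Loss separation target (units of `tau_s`).
#' @param lr_w,lr_theta Adam learning rates for weights and raw delay
#'   parameters.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = none).
#' @param batch_size Minibatch size.
#' @param epochs Number of epochs.
#' @param n_train,n_val,n_test Dataset sizes (regenerated per seed).
#' @param seed Integer seed; fixes data, initialization and shuffling.
#' @param silent_bump Additive weight bump per update applied to incoming
#'   weights of silent hidden/output neurons, scaled by the fraction of the
#'   batch for which the neuron was silent. Revives dead units.
#' @param clip_norm Global gradient-norm clip (set `Inf` to disable).
#' @param freeze_delays If `TRUE`, delay parameters are not updated
#'   (weight-only training on a fixed delay configuration).
#' @param delay_blocks `"all"` or `"first"`, see [build_network()].
#' @param init_mean_scale,init_sd_scale,theta_jitter_sd Initialization,
#'   see [build_network()].
#' @param noise Optional [noise_spec()] for training under the hardware
#'   noise model (forward passes are perturbed; gradients are computed from
#'   the noisy spike times, as in chip-in-the-loop training).
#' @param verbose Print per-epoch progress.
#' @return A list of class `train_config`.
#' @export
train_config <- function(hidden = 30, delay_kind = "none", lambda = 2,
                         span = 2, t0 = 0, tau_ratio = 2, delta_t = 0.2,
                         lr_w = 0.02, lr_theta = 0.03, lr_decay = 0.99,
                         batch_size = 50, epochs = 300,
                         n_train = 5000, n_val = 1000, n_test = 1000,
                         seed = 1, silent_bump = 5e-3, clip_norm = 10,
                         freeze_delays = FALSE,
                         delay_blocks = "all",
                         init_mean_scale = 6, init_sd_scale = 1.5,
                         theta_jitter_sd = 0.1,
                         noise = NULL, verbose = FALSE) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$hidden >= 1), cfg$lambda > 0, cfg$span > 0,
            cfg$delta_t > 0, cfg$lr_w > 0, cfg$lr_theta > 0,
            cfg$lr_decay > 0, cfg$lr_decay <= 1,
            cfg$batch_size >= 1, cfg$epochs >= 0, cfg$n_train >= 1)
  class(cfg) <- "train_config"
  cfg
}

# Adam optimizer state and update for a list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(state, params, grads, lrs,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    params[[i]] <- params[[i]] -
      lrs[[i]] * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(state = state, params = params)
}

clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  sq <- sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2),
                   numeric(1)))
  nrm <- sqrt(sq)
  if (nrm > max_norm) grads <- lapply(grads, function(g)
    if (is.null(g)) NULL else g * (max_norm / nrm))
  grads
}

#' Train a spiking network with exact event-based gradients
#'
#' Minibatch gradient descent (Adam) on all trainable parameters --
#' synaptic weights and, unless frozen, raw delay parameters -- using the
#' exact spike-time gradients of the separation loss. Fully deterministic
#' given the config seed. Training aborts with a diagnostic if the loss
#' diverges to `NaN`.
#'
#' @param dataset A list with `train` and optionally `val` entries, each a
#'   list with `times` (`n x 4` spike matrix) and `labels`. Typically from
#'   [yinyang_dataset()].
#' @param config A [train_config()].
#' @param model Optional pre-built `snn_model` to continue training;
#'   by default a fresh model is initialized from the config seed.
#' @return A list with `model` (final), `best_model` (lowest validation
#'   error checkpoint, final model when no validation set), and `history`
#'   (data frame: epoch, train_loss, train_err, val_err).
#' @export
train_network <- function(dataset, config, model = NULL) {
  set.seed(config$seed)
  cst <- neuron_constants(tau_s = 1, tau_ratio = config$tau_ratio)
  if (is.null(model)) {
    model <- build_network(c(4, config$hidden, 3),
                           delay_kind = config$delay_kind,
                           lambda_bound = config$lambda,
                           constants = cst,
                           init_mean_scale = config$init_mean_scale,
                           init_sd_scale = config$init_sd_scale,
                           theta_jitter_sd = config$theta_jitter_sd,
                           delay_blocks = config$delay_blocks)
  }
  L <- length(model$weights)
  has_theta <- vapply(model$delays, function(d) !is.null(d$theta),
                      logical(1))
  params <- c(model$weights,
              lapply(model$delays, function(d) d$theta %||% matrix(0, 0, 0)))
  opt <- adam_init(params)

  n <- nrow(dataset$train$times)
  nb <- max(1L, ceiling(n / config$batch_size))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_err = numeric(), val_err = numeric())
  best_val <- Inf
  best_model <- model

  pull_params <- function() {
    for (l in seq_len(L)) {
      model$weights[[l]] <<- params[[l]]
      if (has_theta[l]) model$delays[[l]]$theta <<- params[[L + l]]
    }
  }

  for (epoch in seq_len(config$epochs)) {
    decay <- config$lr_decay^(epoch - 1)
    lrs <- c(rep(list(config$lr_w * decay), L),
             rep(list(config$lr_theta * decay), L))
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[seq.int((ib - 1L) * config$batch_size + 1L,
                         min(ib * config$batch_size, n))]
      xb <- dataset$train$times[idx, , drop = FALSE]
      yb <- dataset$train$labels[idx]
      fw <- if (is.null(config$noise)) network_forward(xb, model)
            else perturb_forward(model, xb, config$noise,
                                 trial_seed = sample.int(2^31 - 1, 1))
      lg <- loss_delta_mse_grad(fw$output, yb, config$delta_t)
      if (!is.finite(lg$loss))
        stop(sprintf("training diverged (loss = %g) at epoch %d",
                     lg$loss, epoch), call. = FALSE)
      bw <- network_backward(lg$grad, fw$caches, model)
      grads <- c(bw$dW, lapply(seq_len(L), function(l)
        if (has_theta[l] && !config$freeze_delays) bw$dtheta[[l]] else NULL))
      grads <- clip_global_norm(grads, config$clip_norm)
      st <- adam_step(opt, params, grads, lrs)
      opt <- st$state; params <- st$params
      pull_params()
      # revive silent units: positive bump on incoming weights, scaled by
      # the fraction of the batch for which the neuron stayed silent
      if (config$silent_bump > 0) {
        for (l in seq_len(L)) {
          fs <- colMeans(!is.finite(fw$layers[[l]]))
          if (any(fs > 0)) {
            model$weights[[l]] <- model$weights[[l]] +
              config$silent_bump * rep(fs, each = nrow(model$weights[[l]]))
            params[[l]] <- model$weights[[l]]
          }
        }
      }
      pred <- predict_ttfs(fw$output)
      ep_hits <- ep_hits + sum(!is.na(pred) & pred == yb)
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    train_loss <- ep_loss / n
    train_err <- 100 * (1 - ep_hits / n)
    val_err <- if (!is.null(dataset$val))
      evaluate_network(model, dataset$val) else NA_real_
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = train_loss, train_err = train_err,
      val_err = val_err))
    if (!is.na(val_err) && val_err < best_val) {
      best_val <- val_err
      best_model <- model
    }
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  train err %5.2f%%  val err %s",
                      epoch, train_loss, train_err,
                      if (is.na(val_err)) "-" else
                        sprintf("%5.2f%%", val_err)))
  }
  if (is.null(dataset$val)) best_model <- model
  list(model = model, best_model = best_model, history = history)
}

#' Run one full experiment from a config
#'
#' Generates train/validation/test datasets for the config seed, trains the
#' network, and evaluates the best-validation checkpoint on the test set.
#'
#' @param config A [train_config()].
#' @return A list with `test_err`, `model`, `best_model`, `history`, and
#'   the generated `data`.
#' @export
run_experiment <- function(config) {
  set.seed(config$seed)
  sub <- sample.int(2^31 - 2, 3)
  data <- list(
    train = yinyang_dataset(config$n_train, seed = sub[1],
                            span = config$span, t0 = config$t0),
    val = if (config$n_val > 0)
      yinyang_dataset(config$n_val, seed = sub[2], span = config$span,
                      t0 = config$t0),
    test = yinyang_dataset(config$n_test, seed = sub[3],
                           span = config$span, t0 = config$t0))
  fit <- train_network(data[c("train", "val")], config)
  test_err <- evaluate_network(fit$best_model, data$test)
  list(test_err = test_err, model = fit$model, best_model = fit$best_model,
       history = fit$history, data = data)
}

#' Sweep experiment grids over seeds
#'
#' Runs [run_experiment()] for every combination in the grid and every
#' seed, and returns one tidy row per run with parameter counts attached.
#' Use [sweep_summary()] for per-cell medians and interquartile ranges.
#'
#' @param grid A data frame with any of the columns `hidden`, `delay_kind`,
#'   `lambda`, `span` (missing columns fall back to the base config).
#' @param seeds Integer vector of seeds (the reference study uses 10).
#' @param base_config A [train_config()] supplying all remaining settings.
#' @param verbose Print one line per completed run.
#' @return A data frame with columns `hidden`, `delay_kind`, `lambda`,
#'   `span`, `seed`, `n_params_w`, `n_params_d`, `n_params`, `test_err`.
#' @export
sweep_experiments <- function(grid, seeds, base_config = train_config(),
                              verbose = FALSE) {
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    for (col in intersect(names(grid), c("hidden", "delay_kind", "lambda",
                                         "span"))) {
      cfg[[col]] <- grid[[col]][g]
    }
    for (sd in seeds) {
      cfg$seed <- sd
      res <- run_experiment(cfg)
      pc <- count_parameters(res$best_model)
      rows[[length(rows) + 1L]] <- data.frame(
        hidden = cfg$hidden, delay_kind = cfg$delay_kind,
        lambda = cfg$lambda, span = cfg$span, seed = sd,
        n_params_w = pc$weights, n_params_d = pc$delays,
        n_params = pc$total, test_err = res$test_err)
      if (verbose)
        message(sprintf("hidden=%d kind=%s span=%g seed=%d -> %.2f%%",
                        cfg$hidden, cfg$delay_kind, cfg$span, sd,
                        res$test_err))
    }
  }
  do.call(rbind, rows)
}

#' Summarize a sweep: median and IQR per grid cell
#'
#' @param results Data frame from [sweep_experiments()].
#' @return One row per (hidden, delay_kind, lambda, span) with `median_err`,
#'   `q25`, `q75`, `n_seeds` and parameter counts.
#' @export
sweep_summary <- function(results) {
  key <- interaction(results$hidden, results$delay_kind, results$lambda,
                     results$span, drop = TRUE)
  out <- lapply(split(results, key), function(d) {
    q <- stats::quantile(d$test_err, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(hidden = d$hidden[1], delay_kind = d$delay_kind[1],
               lambda = d$lambda[1], span = d$span[1],
               n_params_w = d$n_params_w[1], n_params_d = d$n_params_d[1],
               n_params = d$n_params[1], n_seeds = nrow(d),
               q25 = q[1], median_err = q[2], q75 = q[3])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$delay_kind, res$hidden, res$span), ]
}
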