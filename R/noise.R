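#' Hardware-noise specification
#'
#' Configurable perturbation model for hardware-aware simulation of analog
#' neuromorphic substrates, covering the three effect families of such
#' systems: trial-to-trial variation (Gaussian jitter on every emitted
#' spike time and on effective delays, redrawn per trial), fixed-pattern
#' noise (static multiplicative weight deviation, frozen per device seed),
#' and digital parameter quantization (weights and delays configured with
#' finite bit depth). Default magnitudes (jitter `0.01 tau_s`, 5 percent
#' fixed-pattern spread) are placeholders for exploring the model's
#' behavior -- they are NOT calibrated to any specific chip.
#'
#' @param spike_jitter_sigma Per-trial Gaussian SD added to every spike
#'   time, inputs included (time units).
#' @param fixed_pattern_sigma Relative SD of the static multiplicative
#'   weight deviation, drawn once per `fp_seed`.
#' @param delay_jitter_sigma Per-trial Gaussian SD on effective delays.
#' @param weight_bits Weight quantization depth (bits); `NULL` disables.
#' @param delay_bits Delay quantization depth (bits); `NULL` disables.
#' @param fp_seed Integer seed freezing the fixed-pattern deviation.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(spike_jitter_sigma = 0.01,
                       fixed_pattern_sigma = 0.05,
                       delay_jitter_sigma = 0,
                       weight_bits = 6L, delay_bits = 8L,
                       fp_seed = 1L) {
  stopifnot(spike_jitter_sigma >= 0, fixed_pattern_sigma >= 0,
            delay_jitter_sigma >= 0,
            is.null(weight_bits) || weight_bits >= 1,
            is.null(delay_bits) || delay_bits >= 1)
  structure(list(spike_jitter_sigma = spike_jitter_sigma,
                 fixed_pattern_sigma = fixed_pattern_sigma,
                 delay_jitter_sigma = delay_jitter_sigma,
                 weight_bits = weight_bits, delay_bits = delay_bits,
                 fp_seed = as.integer(fp_seed)),
            class = "noise_spec")
}

#' Disabled noise specification
#'
#' All sigmas zero, quantization off: the perturbed forward pass is then
#' bit-identical to the clean one.
#' @return A `noise_spec` with every source disabled.
#' @export
noise_off <- function() {
  noise_spec(spike_jitter_sigma = 0, fixed_pattern_sigma = 0,
             delay_jitter_sigma = 0, weight_bits = NULL, delay_bits = NULL)
}

#' Uniform quantization onto a fixed grid
#'
#' Maps values to the nearest of `2^bits` uniformly spaced levels spanning
#' `value_range` (both endpoints representable), clamping values outside
#' the range. Idempotent; the quantization error is at most half a step.
#'
#' @param values Numeric vector/matrix.
#' @param bits Bit depth (levels = `2^bits`); `NULL` returns the input
#'   unchanged.
#' @param value_range Length-2 numeric, finite, `range[1] < range[2]`.
#' @return Quantized values, same shape.
#' @export
quantize <- function(values, bits, value_range) {
  if (is.null(bits)) return(values)
  stopifnot(bits >= 1, length(value_range) == 2L, all(is.finite(value_range)),
            value_range[1] < value_range[2])
  step <- diff(value_range) / (2^bits - 1)
  q <- value_range[1] + round((values - value_range[1]) / step) * step
  pmin(pmax(q, value_range[1]), value_range[2])
}

# Build the noisy (fixed-pattern + quantized) parameter copy of a model.
apply_parameter_noise <- function(model, spec) {
  if (spec$fixed_pattern_sigma > 0) {
    rs <- local_rng(spec$fp_seed)
    for (l in seq_along(model$weights)) {
      fp <- matrix(stats::rnorm(length(model$weights[[l]]), 0,
                                spec$fixed_pattern_sigma),
                   nrow(model$weights[[l]]))
      model$weights[[l]] <- model$weights[[l]] * (1 + fp)
    }
    restore_rng(rs)
  }
  if (!is.null(spec$weight_bits)) {
    for (l in seq_along(model$weights)) {
      wmax <- max(abs(model$weights[[l]]), 1e-12)
      model$weights[[l]] <- quantize(model$weights[[l]], spec$weight_bits,
                                     c(-wmax, wmax))
    }
  }
  model
}

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  else if (exists(".Random.seed", .GlobalEnv))
    rm(".Random.seed", envir = .GlobalEnv)
}

#' Forward pass under the hardware-noise model
#'
#' Applies fixed-pattern weight deviation and parameter quantization to a
#' copy of the model, perturbs effective delays with trial jitter, then
#' runs the event-based forward pass adding Gaussian jitter to every spike
#' time (inputs and each neuron layer's outputs) before it feeds the next
#' layer. Noise touches spike times and parameters only -- never membrane
#' state -- so the event-based contract is preserved. Identical spec and
#' seeds give identical output.
#'
#' @param model An `snn_model`.
#' @param batch `B x n_in` input spike-time matrix.
#' @param spec A [noise_spec()].
#' @param trial_seed Integer seed for the trial-to-trial noise draws.
#' @return As [network_forward()]: list with `output`, `layers`, `caches`.
#' @export
perturb_forward <- function(model, batch, spec, trial_seed = 1L) {
  noisy <- apply_parameter_noise(model, spec)
  rs <- local_rng(trial_seed)
  on.exit(restore_rng(rs))
  for (l in seq_along(noisy$delays)) {
    p <- noisy$delays[[l]]
    if (p$kind == "none") next
    d <- effective_delays(p)
    d <- quantize(d, spec$delay_bits, c(0, p$lambda))
    if (spec$delay_jitter_sigma > 0)
      d <- pmax(d + stats::rnorm(length(d), 0, spec$delay_jitter_sigma), 0)
    # store perturbed delays by inverting the reparameterization (clamped
    # inside the open interval so the logistic map stays invertible)
    frac <- pmin(pmax(d / p$lambda, 1e-9), 1 - 1e-9)
    noisy$delays[[l]]$theta[] <- log(frac / (1 - frac))
  }
  jitter_fn <- if (spec$spike_jitter_sigma > 0) {
    function(tm) {
      fin <- is.finite(tm)
      tm[fin] <- tm[fin] + stats::rnorm(sum(fin), 0, spec$spike_jitter_sigma)
      tm
    }
  } else NULL
  network_forward(batch, noisy, jitter_fn = jitter_fn)
}

#' Evaluate a model under repeated noisy trials
#'
#' Runs [perturb_forward()] `trials` times with distinct trial seeds and
#' scores the TTFS prediction each time, giving the distribution of the
#' noisy test error.
#'
#' @param model An `snn_model`.
#' @param dataset A list with `times` and `labels`.
#' @param spec A [noise_spec()].
#' @param trials Number of repeated trials (>= 1).
#' @param seed Base seed; trial t uses `seed + t`.
#' @return A list with `errors` (per-trial error, percent), `median` and
#'   `iqr`.
#' @export
noisy_evaluate <- function(model, dataset, spec, trials = 10, seed = 1L) {
  stopifnot(trials >= 1)
  errs <- vapply(seq_len(trials), function(tr) {
    out <- perturb_forward(model, dataset$times, spec,
                           trial_seed = seed + tr)$output
    pred <- predict_ttfs(out)
    100 * mean(is.na(pred) | pred != dataset$labels)
  }, numeric(1))
  q <- stats::quantile(errs, c(0.25, 0.5, 0.75), names = FALSE)
  list(errors = errs, median = q[2], iqr = c(q25 = q[1], q75 = q[3]))
}
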