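#' Trainable delay parameters for one connection block
#'
#' Transmission delays are parameterized per connection block (the
#' connections between two consecutive neuron layers) in one of four kinds:
#' `"none"` (no delays), `"axonal"` (one delay per presynaptic neuron,
#' applied to its outgoing spike), `"dendritic"` (one delay per postsynaptic
#' neuron, applied to all its incoming spikes), and `"synaptic"` (one delay
#' per individual connection). Raw parameters `theta` are mapped to
#' effective delays by the bounded logistic reparameterization
#' \eqn{d = \lambda\,\sigma(\theta)}, so delays always lie in
#' `(0, lambda)`.
#'
#' @param kind One of `"none"`, `"axonal"`, `"dendritic"`, `"synaptic"`.
#' @param n_pre,n_post Block dimensions (presynaptic and postsynaptic
#'   neuron counts).
#' @param lambda_bound Maximum delay \eqn{\lambda} (time units).
#' @param theta Optional raw parameter values; defaults to 0 (delay
#'   `lambda/2`). Shape must match the kind: `n_pre x 1` (axonal),
#'   `1 x n_post` (dendritic), `n_pre x n_post` (synaptic).
#' @return An object of class `delay_params`.
#' @export
delay_params <- function(kind = c("none", "axonal", "dendritic", "synaptic"),
                         n_pre, n_post, lambda_bound = 1, theta = NULL) {
  kind <- match.arg(kind)
  stopifnot(lambda_bound > 0)
  shape <- switch(kind,
    none = NULL,
    axonal = c(n_pre, 1L),
    dendritic = c(1L, n_post),
    synaptic = c(n_pre, n_post))
  if (is.null(shape)) {
    theta <- NULL
  } else if (is.null(theta)) {
    theta <- matrix(0, shape[1L], shape[2L])
  } else {
    theta <- matrix(as.numeric(theta), shape[1L], shape[2L])
  }
  structure(list(kind = kind, theta = theta, lambda = lambda_bound,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post)),
            class = "delay_params")
}

#' Effective delays of a delay block
#'
#' @param params A [delay_params()] object.
#' @return Numeric array of effective delays `lambda * sigmoid(theta)` in
#'   the kind's natural shape, or `NULL` for `kind = "none"`.
#' @export
effective_delays <- function(params) {
  if (params$kind == "none") return(NULL)
  params$lambda * sigmoid(params$theta)
}

#' Forward pass of a delay layer
#'
#' Adds effective delays to the incoming spike times, `t_d = t + d`.
#' Axonal delays shift each presynaptic neuron's output once; dendritic and
#' synaptic delays produce per-postsynaptic-neuron arrival times, returned
#' as an expanded arrival structure consumed by [layer_forward()]. Silent
#' inputs (`Inf`) remain silent under any delay.
#'
#' @param input_spikes Length-`pre` vector or `B x pre` matrix of spike
#'   times.
#' @param params A [delay_params()] object.
#' @return An arrival structure: list with `arr` (matrix of arrival times),
#'   `B`, `N`, `shared` (`TRUE` when rows are per-sample, `FALSE` when
#'   expanded to one row per sample/post pair) and, if expanded, `P`.
#' @export
delay_forward <- function(input_spikes, params) {
  tm <- if (is.matrix(input_spikes)) input_spikes else
    matrix(input_spikes, nrow = 1L)
  B <- nrow(tm); N <- ncol(tm)
  if (N != params$n_pre && params$kind != "none")
    stop("input width does not match delay block", call. = FALSE)
  d <- effective_delays(params)
  switch(params$kind,
    none = list(arr = tm, B = B, N = N, shared = TRUE),
    axonal = list(arr = tm + rep(as.vector(d), each = B), B = B, N = N,
                  shared = TRUE),
    dendritic = {
      P <- params$n_post
      # rows (p-1)*B + b of the expanded structure all receive shift d_p
      shift <- rep(as.vector(d), each = B)
      arr <- tm[rep(seq_len(B), P), , drop = FALSE] + shift
      list(arr = arr, B = B, N = N, P = P, shared = FALSE)
    },
    synaptic = {
      P <- params$n_post
      arr <- tm[rep(seq_len(B), P), , drop = FALSE]
      # d[i, p] added to column i of block p
      shift <- t(d)[rep(seq_len(P), each = B), , drop = FALSE]
      list(arr = arr + shift, B = B, N = N, P = P, shared = FALSE)
    })
}

#' Construct a feed-forward spiking network model
#'
#' Builds the alternating delay/neuron layer stack: each connection block
#' consists of a delay layer followed by a neuron layer. Weights are drawn
#' from a normal distribution whose mean scales inversely with fan-in,
#' tuned so that hidden and output neurons fire for the majority of inputs
#' at initialization (time-to-first-spike networks cannot learn from silent
#' units). Raw delay parameters start at 0 (effective delay `lambda/2`)
#' with small jitter to break symmetry.
#'
#' @param sizes Integer vector of layer sizes, e.g. `c(4, 30, 3)`.
#' @param delay_kind Delay taxonomy for every block: `"none"`, `"axonal"`,
#'   `"dendritic"` or `"synaptic"`.
#' @param lambda_bound Maximum delay \eqn{\lambda} (time units).
#' @param constants A [neuron_constants()] object shared by all neurons.
#' @param init_mean_scale,init_sd_scale Weight initialization: weights are
#'   `N(init_mean_scale / fan_in, (init_sd_scale / sqrt(fan_in))^2)`.
#' @param theta_jitter_sd Standard deviation of the initial jitter on raw
#'   delay parameters.
#' @param delay_blocks Which blocks carry delays: `"all"` (default) or
#'   `"first"` (input block only).
#' @return An object of class `snn_model`.
#' @export
build_network <- function(sizes = c(4, 30, 3),
                          delay_kind = "none",
                          lambda_bound = 1,
                          constants = neuron_constants(),
                          init_mean_scale = 6,
                          init_sd_scale = 1.5,
                          theta_jitter_sd = 0.1,
                          delay_blocks = c("all", "first")) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  delay_blocks <- match.arg(delay_blocks)
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  delays <- vector("list", L)
  for (l in seq_len(L)) {
    n_pre <- sizes[l]; n_post <- sizes[l + 1L]
    mu <- init_mean_scale / n_pre
    sdv <- init_sd_scale / sqrt(n_pre)
    weights[[l]] <- matrix(stats::rnorm(n_pre * n_post, mu, sdv),
                           n_pre, n_post)
    kind_l <- if (delay_blocks == "first" && l > 1L) "none" else delay_kind
    delays[[l]] <- delay_params(kind_l, n_pre, n_post, lambda_bound)
    if (!is.null(delays[[l]]$theta) && theta_jitter_sd > 0)
      delays[[l]]$theta[] <- stats::rnorm(length(delays[[l]]$theta),
                                          0, theta_jitter_sd)
  }
  structure(list(sizes = as.integer(sizes), weights = weights,
                 delays = delays, constants = constants,
                 delay_kind = delay_kind, lambda = lambda_bound),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("spiking network %s, delays: %s (lambda = %g)\n",
              paste(x$sizes, collapse = "-"), x$delay_kind, x$lambda))
  cat(sprintf("  parameters: %d weights + %d delays = %d\n",
              pc$weights, pc$delays, pc$total))
  invisible(x)
}

#' Full forward pass through the delay/neuron stack
#'
#' Propagates input spike times through alternating delay and neuron layers
#' of arbitrary depth. Between layers only spike times are transmitted;
#' caches carry what the backward pass needs.
#'
#' @param input_spikes `B x n_in` matrix (or length-`n_in` vector) of input
#'   spike times.
#' @param model An [build_network()] model.
#' @param jitter_fn Optional function(times-matrix) -> times-matrix applied
#'   to every layer's emitted spike times (used by the hardware-noise
#'   simulation mode); `NULL` for the clean path.
#' @return A list with `output` (`B x n_out` spike-time matrix), `layers`
#'   (spike times of every neuron layer) and `caches`.
#' @export
network_forward <- function(input_spikes, model, jitter_fn = NULL) {
  tm <- if (is.matrix(input_spikes)) input_spikes else
    matrix(input_spikes, nrow = 1L)
  if (!is.null(jitter_fn)) tm <- jitter_fn(tm)
  L <- length(model$weights)
  caches <- vector("list", L)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    a <- delay_forward(tm, model$delays[[l]])
    fw <- layer_forward(NULL, model$weights[[l]], model$constants,
                        arrivals = a)
    tm <- if (is.matrix(fw$times)) fw$times else matrix(fw$times, nrow = 1L)
    if (!is.null(jitter_fn)) tm <- jitter_fn(tm)
    layers[[l]] <- tm
    caches[[l]] <- fw$cache
  }
  list(output = tm, layers = layers, caches = caches)
}

#' Full backward pass through the delay/neuron stack
#'
#' Alternates [neuron_backward()] and [delay_backward()] from the loss down
#' to the inputs, accumulating gradients for every weight matrix and every
#' raw delay parameter (chained through the logistic reparameterization).
#'
#' @param loss_grads `B x n_out` matrix of \eqn{\partial L/\partial t} at
#'   the output spike times.
#' @param caches Caches from [network_forward()] of the same batch.
#' @param model The model used in the forward pass.
#' @return A list with `dW` (list of weight gradients), `dtheta` (list of
#'   raw-delay gradients, `NULL` entries for `kind = "none"`), and
#'   `dL_dt_input` (`B x n_in` gradient at the input spike times).
#' @export
network_backward <- function(loss_grads, caches, model) {
  L <- length(model$weights)
  up <- if (is.matrix(loss_grads)) loss_grads else
    matrix(loss_grads, nrow = 1L)
  dW <- vector("list", L)
  dtheta <- vector("list", L)
  for (l in rev(seq_len(L))) {
    nb <- neuron_backward(up, caches[[l]])
    dW[[l]] <- nb$dW
    db <- delay_backward(nb$dL_darr, model$delays[[l]], caches[[l]]$B)
    if (!is.null(db$dd)) {
      dtheta[[l]] <- db$dd * reparam_grad(model$delays[[l]]$theta,
                                          model$delays[[l]]$lambda)
    }
    up <- db$dL_dt_in
  }
  list(dW = dW, dtheta = dtheta, dL_dt_input = up)
}

#' Count trainable parameters
#'
#' Weight counts scale with `pre * post` per block; delay counts follow the
#' taxonomy's natural shapes: per presynaptic neuron (axonal), per
#' postsynaptic neuron (dendritic), per connection (synaptic). Axonal and
#' dendritic delay memory thus scales linearly with network width, synaptic
#' delay memory quadratically.
#'
#' @param model An `snn_model`.
#' @return A list with `weights`, `delays` and `total` counts.
#' @examples
#' m <- build_network(c(4, 30, 3), delay_kind = "synaptic")
#' count_parameters(m)  # 210 weights + 210 delays
#' @export
count_parameters <- function(model) {
  w <- sum(vapply(model$weights, length, integer(1)))
  d <- sum(vapply(model$delays, function(p) length(p$theta %||% numeric()),
                  integer(1)))
  list(weights = w, delays = d, total = w + d)
}

#' Serialize a model to JSON
#'
#' Full-precision, round-trip-exact serialization of layer sizes, neuron
#' constants, weights, raw delay parameters, delay kind and bound.
#'
#' @param model An `snn_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    package = "snndelays",
    version = as.character(utils::packageVersion("snndelays")),
    sizes = model$sizes,
    delay_kind = model$delay_kind,
    lambda = model$lambda,
    constants = model$constants[c("tau_s", "tau_ratio", "threshold", "leak")],
    weights = lapply(model$weights, function(w)
      list(dim = dim(w), data = as.vector(w))),
    delays = lapply(model$delays, function(p)
      list(kind = p$kind, lambda = p$lambda, n_pre = p$n_pre,
           n_post = p$n_post,
           theta = if (is.null(p$theta)) NULL else
             list(dim = dim(p$theta), data = as.vector(p$theta)))))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a model from JSON
#'
#' @param x A JSON string or a path to a JSON file written by
#'   [model_to_json()].
#' @return The reconstructed `snn_model`.
#' @export
model_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  cst <- neuron_constants(tau_s = doc$constants$tau_s,
                          tau_ratio = doc$constants$tau_ratio,
                          threshold = doc$constants$threshold,
                          leak = doc$constants$leak)
  rebuild <- function(entry)
    matrix(unlist(entry$data), entry$dim[[1]], entry$dim[[2]])
  W <- lapply(doc$weights, rebuild)
  dl <- lapply(doc$delays, function(p)
    delay_params(p$kind, p$n_pre, p$n_post, p$lambda,
                 theta = if (is.null(p$theta)) NULL else rebuild(p$theta)))
  structure(list(sizes = as.integer(unlist(doc$sizes)), weights = W,
                 delays = dl, constants = cst,
                 delay_kind = doc$delay_kind, lambda = doc$lambda),
            class = "snn_model")
}
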