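#' Exact spike-time derivatives for one neuron
#'
#' Differentiates the closed-form first-spike time of a solved neuron with
#' respect to its input weights and arrival times. For `tau_ratio = 2`,
#' with \eqn{\sqrt{D} = \sqrt{a_2^2 - 4 a_1 g_\ell\vartheta}},
#' \deqn{\frac{\partial T}{\partial a_1} =
#'   \frac{\tau_s (a_2 + \sqrt{D})}{a_1 \sqrt{D}}, \qquad
#'   \frac{\partial T}{\partial a_2} = -\frac{2\tau_s}{\sqrt{D}},}
#' chained through the exponential-sum coefficients. For `tau_ratio = 1` the
#' derivative of the Lambert W function,
#' \eqn{\mathcal{W}'(x) = \mathcal{W}/(x(1+\mathcal{W}))}, gives
#' \eqn{\partial T/\partial b = \tau_s / (a_1 (1 + \mathcal{W}))} and the
#' matching `a1` partial. Non-causal inputs (arriving at or after `T`) have
#' exactly zero gradient. The derivatives depend only on spike times,
#' weights and constants -- no membrane state.
#'
#' @param solution A `causal_solution` from [first_spike()] with a finite
#'   spike time.
#' @param weights,arrival_times The inputs the solution was computed from.
#' @param constants A [neuron_constants()] object.
#' @return A list with `dT_dw` and `dT_dt`, numeric vectors aligned with
#'   the inputs (zeros at non-causal positions).
#' @export
neuron_grads <- function(solution, weights, arrival_times, constants) {
  if (!is.finite(solution$spike_time))
    stop("no gradient: silent neuron", call. = FALSE)
  n <- length(weights)
  dT_dw <- numeric(n)
  dT_dt <- numeric(n)
  ci <- solution$causal_indices
  w <- weights[ci]; t <- arrival_times[ci]
  ts <- constants$tau_s
  co <- solution$coeffs
  if (constants$tau_ratio == 2L) {
    D <- co$a2^2 - 4 * co$a1 * constants$threshold
    sq <- sqrt(max(D, 0))
    sq <- max(sq, .GRAD_FLOOR)          # tangency: derivative is unbounded
    dTda1 <- ts * (co$a2 + sq) / (co$a1 * sq)
    dTda2 <- -2 * ts / sq
    e1 <- exp(t / ts); e2 <- exp(t / (2 * ts))
    dT_dw[ci] <- dTda1 * 2 * e1 + dTda2 * 2 * e2
    dT_dt[ci] <- dTda1 * (2 * w / ts) * e1 + dTda2 * (w / (2 * ts)) * 2 * e2
  } else {
    larg <- log(constants$threshold / co$a1) + co$b / co$a1
    w0 <- lambert_w0(-exp(min(larg, -1)))
    opw <- max(1 + w0, .GRAD_FLOOR)
    dTda1 <- (ts / co$a1) * (-co$b / co$a1 + w0 * (1 + co$b / co$a1) / opw)
    dTdb <- ts / (co$a1 * opw)
    e1 <- exp(t / ts)
    dT_dw[ci] <- dTda1 * e1 + dTdb * (t / ts) * e1
    dT_dt[ci] <- (w / ts) * e1 * (dTda1 + dTdb * (1 + t / ts))
  }
  list(dT_dw = dT_dw, dT_dt = dT_dt)
}

# Gradient magnitudes diverge at grazing (tangent) crossings; the exact
# piecewise gradient is kept, merely floored away from a literal division
# by zero. Global norm clipping in the optimizer bounds the step.
.GRAD_FLOOR <- 1e-150

# Batched per-row partials dT/dw and dT/dt in ORIGINAL input-column order,
# from a layer_forward cache. Silent rows contribute zeros.
layer_partials <- function(cache) {
  sol <- cache$sol
  cst <- cache$constants
  ts <- cst$tau_s
  M <- nrow(sol$sorted_t); N <- ncol(sol$sorted_t)
  fin <- is.finite(sol$spike_time)
  # causal mask in sorted space: position <= accepted k, usable arrivals
  causal <- (matrix(rep(seq_len(N), each = M), M, N) <=
               matrix(sol$k, M, N)) & sol$usable & fin
  Tz <- ifelse(sol$usable, sol$sorted_t, 0)
  Wz <- ifelse(sol$usable, sol$sorted_w, 0)
  if (cst$tau_ratio == 2L) {
    sq <- pmax(sol$sqrtD, .GRAD_FLOOR)
    dTda1 <- ifelse(fin, ts * (sol$a2 + sq) / (sol$a1 * sq), 0)
    dTda2 <- ifelse(fin, -2 * ts / sq, 0)
    e1 <- exp(Tz / ts); e2 <- exp(Tz / (2 * ts))
    dw_s <- (dTda1 * 2 * e1 + dTda2 * 2 * e2) * causal
    dt_s <- (dTda1 * (2 * Wz / ts) * e1 + dTda2 * (Wz / ts) * e2) * causal
  } else {
    opw <- pmax(1 + sol$w0, .GRAD_FLOOR)
    ba <- sol$b / sol$a1
    dTda1 <- ifelse(fin, (ts / sol$a1) * (-ba + sol$w0 * (1 + ba) / opw), 0)
    dTdb <- ifelse(fin, ts / (sol$a1 * opw), 0)
    e1 <- exp(Tz / ts)
    dw_s <- (dTda1 * e1 + dTdb * (Tz / ts) * e1) * causal
    dt_s <- ((Wz / ts) * e1 * (dTda1 + dTdb * (1 + Tz / ts))) * causal
  }
  # scatter sorted-order partials back to original input columns
  sel <- cbind(rep(seq_len(M), times = N), as.vector(sol$sort_col))
  dTdw <- matrix(0, M, N); dTdw[sel] <- as.vector(dw_s)
  dTdt <- matrix(0, M, N); dTdt[sel] <- as.vector(dt_s)
  list(dTdw = dTdw, dTdt = dTdt)
}

#' Backward pass of one neuron layer
#'
#' Chains an upstream loss gradient with respect to the layer's output spike
#' times through the exact per-neuron partials, producing the weight
#' gradient and the loss gradient with respect to the layer's (delayed)
#' arrival times. Silent neurons propagate zero gradient.
#'
#' @param upstream `B x post` matrix (or length-`post` vector) of
#'   \eqn{\partial L / \partial T} for the layer's outputs.
#' @param cache Cache from [layer_forward()] of the same batch.
#' @return A list with `dW` (`pre x post` weight gradient, summed over the
#'   batch), `dL_darr` (`(B*post) x pre` gradient at the expanded arrival
#'   times, consumed by [delay_backward()]), and `dL_dt_in` (`B x pre`
#'   gradient at the presynaptic spike times, already summed over posts).
#' @export
neuron_backward <- function(upstream, cache) {
  B <- cache$B; P <- cache$P; N <- cache$N
  up <- if (is.matrix(upstream)) upstream else matrix(upstream, nrow = 1L)
  if (nrow(up) != B || ncol(up) != P)
    stop("upstream gradient shape does not match cache", call. = FALSE)
  pp <- layer_partials(cache)
  upv <- as.vector(up)                      # m = (p-1)*B + b ordering
  G <- pp$dTdw * upv
  H <- pp$dTdt * upv
  dW <- t(rowsum(G, group = rep(seq_len(P), each = B), reorder = TRUE))
  dL_dt_in <- rowsum(H, group = rep(seq_len(B), times = P), reorder = TRUE)
  dimnames(dW) <- NULL
  dimnames(dL_dt_in) <- NULL
  list(dW = dW, dL_darr = H, dL_dt_in = dL_dt_in)
}

#' Backward pass of a delay layer
#'
#' Transmission delays are additive in spike times, so their derivatives are
#' identity pass-throughs: \eqn{\partial t^d/\partial t = 1} and
#' \eqn{\partial t^d/\partial d = 1}. The gradient for a shared delay
#' parameter (axonal: one per presynaptic neuron; dendritic: one per
#' postsynaptic neuron) is the sum of the upstream gradient over all
#' connection paths sharing it; synaptic delays have one parameter per
#' connection. Gradients at silent inputs are zero (their paths carry no
#' upstream signal).
#'
#' @param dL_darr `(B*post) x pre` upstream gradient at the delayed arrival
#'   times (from [neuron_backward()]), or `B x pre` for `kind` `"none"` /
#'   `"axonal"` when no post expansion was used.
#' @param params A [delay_params()] object.
#' @param B Batch size.
#' @return A list with `dd` (gradient with respect to the effective delays,
#'   shaped like the delay parameters; `NULL` for `kind = "none"`) and
#'   `dL_dt_in` (`B x pre` gradient at the undelayed input times).
#' @export
delay_backward <- function(dL_darr, params, B) {
  M <- nrow(dL_darr); N <- ncol(dL_darr)
  P <- M %/% B
  collapse <- function(H) {
    if (M == B) H
    else rowsum(H, group = rep(seq_len(B), times = P), reorder = TRUE)
  }
  Hb <- collapse(dL_darr)
  dimnames(Hb) <- NULL
  dd <- switch(params$kind,
    none = NULL,
    axonal = matrix(colSums(Hb), ncol = 1L),
    dendritic = {
      per_p <- rowsum(rowSums(dL_darr), group = rep(seq_len(P), each = B),
                      reorder = TRUE)
      matrix(as.vector(per_p), nrow = 1L)
    },
    synaptic = {
      t(rowsum(dL_darr, group = rep(seq_len(P), each = B), reorder = TRUE))
    })
  if (!is.null(dd)) dimnames(dd) <- NULL
  list(dd = dd, dL_dt_in = Hb)
}

#' Gradient of the bounded delay reparameterization
#'
#' Effective delays are kept in `(0, lambda)` through a logistic
#' reparameterization \eqn{d = \lambda\,\sigma(\theta_d)}; this returns
#' \eqn{\partial d/\partial\theta_d = \lambda\,\sigma(\theta_d)
#' (1-\sigma(\theta_d))}.
#'
#' @param theta_d Raw delay parameter(s), any numeric shape.
#' @param lambda_bound Maximum delay \eqn{\lambda > 0} (time units).
#' @return Derivative(s), same shape as `theta_d`.
#' @export
reparam_grad <- function(theta_d, lambda_bound) {
  stopifnot(lambda_bound > 0)
  s <- sigmoid(theta_d)
  lambda_bound * s * (1 - s)
}
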