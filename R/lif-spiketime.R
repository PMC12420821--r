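#' Closed-form threshold-crossing coefficients for a causal input set
#'
#' For a fixed set of causal inputs (those assumed to arrive before the
#' output spike) the membrane trajectory of the normalized LIF model reduces
#' to an analytic threshold-crossing equation whose coefficients are simple
#' exponential sums over the causal inputs. For `tau_ratio = 2` these are
#' \deqn{a_1 = 2\sum_i w_i e^{t_i/\tau_s}, \quad
#'       a_2 = 2\sum_i w_i e^{t_i/(2\tau_s)}}
#' and the crossing satisfies \eqn{a_2 z - a_1 z^2 = g_\ell\vartheta} with
#' \eqn{z = e^{-T/(2\tau_s)}}. For `tau_ratio = 1` (alpha kernel) they are
#' \deqn{a_1 = \sum_i w_i e^{t_i/\tau_s}, \quad
#'       b = \sum_i w_i (t_i/\tau_s) e^{t_i/\tau_s}}
#' with crossing \eqn{(a_1 T/\tau_s - b)e^{-T/\tau_s} = g_\ell\vartheta}.
#' Both forms are validated against numerical integration of the membrane
#' ODE in the test suite.
#'
#' @param weights Numeric vector of synaptic weights, one per input.
#' @param arrival_times Numeric vector of input arrival times (same length).
#' @param causal_indices Integer indices of the inputs assumed causal.
#' @param constants A [neuron_constants()] object.
#' @return A list with `a1` and either `a2` (`tau_ratio = 2`) or `b`
#'   (`tau_ratio = 1`), plus `tau_ratio`.
#' @seealso [spike_time_ratio2()], [spike_time_ratio1()], [first_spike()]
#' @export
causal_coefficients <- function(weights, arrival_times, causal_indices,
                                constants) {
  if (length(causal_indices) == 0L)
    stop("no causal input: empty causal set", call. = FALSE)
  w <- weights[causal_indices]
  t <- arrival_times[causal_indices]
  if (any(!is.finite(t)))
    stop("causal arrival times must be finite", call. = FALSE)
  ts <- constants$tau_s
  if (constants$tau_ratio == 2L) {
    list(a1 = 2 * sum(w * exp(t / ts)),
         a2 = 2 * sum(w * exp(t / (2 * ts))),
         tau_ratio = 2L)
  } else {
    list(a1 = sum(w * exp(t / ts)),
         b  = sum(w * (t / ts) * exp(t / ts)),
         tau_ratio = 1L)
  }
}

#' First-spike time from crossing coefficients, tau_m = 2 tau_s
#'
#' Solves the quadratic threshold-crossing condition
#' \eqn{a_1 z^2 - a_2 z + g_\ell\vartheta = 0}, \eqn{z = e^{-T/(2\tau_s)}},
#' and returns the earliest upward crossing
#' \deqn{T = 2\tau_s \ln\!\left[\frac{2 a_1}{a_2 +
#'   \sqrt{a_2^2 - 4 a_1 g_\ell\vartheta}}\right].}
#' The larger root in `z` is the first crossing in time. No real crossing
#' (negative discriminant, `a1 <= 0`, or non-positive logarithm argument)
#' yields the silent sentinel `Inf` -- non-crossing is a value, not an
#' error. Discriminants within a relative `1e-12` band below zero are
#' treated as exact tangency.
#'
#' @param coeffs Coefficient list from [causal_coefficients()] (`a1`, `a2`).
#' @param constants A [neuron_constants()] object with `tau_ratio = 2`.
#' @return Spike time (numeric scalar) or `Inf` if no crossing.
#' @export
spike_time_ratio2 <- function(coeffs, constants) {
  a1 <- coeffs$a1; a2 <- coeffs$a2
  thr <- constants$threshold
  if (!is.finite(a1) || !is.finite(a2) || a1 <= 0) return(SILENT)
  D <- a2^2 - 4 * a1 * thr
  eps <- 1e-12 * max(a2^2, abs(4 * a1 * thr))
  if (D < -eps) return(SILENT)
  den <- a2 + sqrt(max(D, 0))
  if (den <= 0) return(SILENT)
  2 * constants$tau_s * log(2 * a1 / den)
}

#' First-spike time from crossing coefficients, tau_m = tau_s
#'
#' Inverts the alpha-kernel crossing condition via the Lambert W function:
#' \deqn{T = \tau_s\left\{\frac{b}{a_1} - \mathcal{W}\!\left[
#'   -\frac{g_\ell\vartheta}{a_1}\exp\!\left(\frac{b}{a_1}\right)\right]
#'   \right\}.}
#' The principal branch selects the rising-flank (earliest) crossing; this
#' choice is asserted against the numerical membrane oracle in the tests
#' rather than trusted from the derivation. The W argument is evaluated in
#' log space so that large `b/a1` cannot overflow. Arguments below `-1/e`
#' (kernel maximum below threshold) yield the silent sentinel.
#'
#' @param coeffs Coefficient list from [causal_coefficients()] (`a1`, `b`).
#' @param constants A [neuron_constants()] object with `tau_ratio = 1`.
#' @return Spike time (numeric scalar) or `Inf` if no crossing.
#' @export
spike_time_ratio1 <- function(coeffs, constants) {
  a1 <- coeffs$a1; b <- coeffs$b
  thr <- constants$threshold
  if (!is.finite(a1) || !is.finite(b) || a1 <= 0) return(SILENT)
  # crossing exists iff -arg <= 1/e, i.e. log(-arg) <= -1
  larg <- log(thr / a1) + b / a1
  if (larg > -1 + 1e-12) return(SILENT)
  arg <- -exp(min(larg, -1))
  w0 <- lambert_w0(arg)
  constants$tau_s * (b / a1 - w0)
}

#' Principal-branch Lambert W function
#'
#' Vectorized evaluation of \eqn{\mathcal{W}_0}, the inverse of
#' \eqn{w e^w} on \eqn{[-1, \infty)}, by Halley iteration with a
#' branch-point series initial guess near \eqn{-1/e} and a hard iteration
#' cap, so convergence is guaranteed for every representable argument in
#' the domain (the spike-time inversion only ever needs
#' \eqn{x \in [-1/e, 0)}).
#'
#' @param x Numeric vector, `x >= -1/e` (values within one rounding step
#'   below are clamped to the branch point).
#' @return \eqn{\mathcal{W}_0(x)}, same shape as `x`.
#' @export
lambert_w0 <- function(x) {
  if (any(x < -exp(-1) - 1e-12, na.rm = TRUE))
    stop("lambert_w0: argument below -1/e", call. = FALSE)
  x <- pmax(x, -exp(-1))
  w <- numeric(length(x))
  nb <- x < -0.25
  # series around the branch point: W0 = -1 + p - p^2/3 + 11 p^3/72 + ...
  p <- sqrt(2 * (exp(1) * x[nb] + 1))
  w[nb] <- -1 + p - p^2 / 3 + (11 / 72) * p^3
  w[!nb] <- x[!nb] * (1 - x[!nb])       # W0(x) = x - x^2 + O(x^3)
  for (it in 1:80) {
    ew <- exp(w)
    res <- w * ew - x
    den <- ew * (w + 1) - (w + 2) * res / (2 * w + 2)
    dw <- ifelse(res == 0 | den == 0, 0, res / den)
    w <- w - dw
    if (all(abs(dw) <= 1e-15 * (1 + abs(w)))) break
  }
  w
}

#' Event-based first-spike solve for one neuron
#'
#' Finds the first threshold crossing of a LIF neuron receiving weighted
#' input spikes, by searching over candidate causal sets: arrivals are
#' sorted ascending (stable in input index), and for each prefix of k
#' arrivals the closed-form crossing is computed and accepted iff it falls
#' in the validity window \eqn{t_{(k)} \le T < t_{(k+1)}} (boundaries taken
#' with relative tolerance `1e-12`). Silent (infinite) arrivals are ignored.
#' If no prefix is consistent the neuron is silent.
#'
#' @param arrival_times Numeric vector of input arrival times; `Inf` marks
#'   silent inputs. `NaN` is an error.
#' @param weights Numeric vector of synaptic weights (same length).
#' @param constants A [neuron_constants()] object.
#' @return An object of class `causal_solution`: a list with `spike_time`
#'   (finite or `Inf`), `causal_indices` (original input indices arriving
#'   before the spike), `coeffs` (the accepted coefficient bundle, `NULL`
#'   if silent), and `tau_ratio`.
#' @examples
#' nc <- neuron_constants(tau_ratio = 2)
#' first_spike(c(0, 1), c(3, -5), nc)$spike_time  # inhibition arrives late
#' @export
first_spike <- function(arrival_times, weights, constants) {
  if (length(arrival_times) != length(weights))
    stop("arrival_times and weights must have equal length", call. = FALSE)
  if (any(is.nan(arrival_times)) || any(is.nan(weights)))
    stop("NaN in inputs", call. = FALSE)
  if (length(weights) == 0L)
    return(structure(list(spike_time = SILENT, causal_indices = integer(),
                          coeffs = NULL, tau_ratio = constants$tau_ratio),
                     class = "causal_solution"))
  sol <- solve_arrivals(matrix(arrival_times, nrow = 1L),
                        matrix(weights, nrow = 1L), constants)
  k <- sol$k[1L]
  if (!is.finite(sol$spike_time[1L])) {
    coeffs <- NULL
    causal <- integer()
  } else {
    causal <- sort(sol$sort_col[1L, seq_len(k)])
    coeffs <- if (constants$tau_ratio == 2L) {
      list(a1 = sol$a1[1L], a2 = sol$a2[1L], tau_ratio = 2L)
    } else {
      list(a1 = sol$a1[1L], b = sol$b[1L], tau_ratio = 1L)
    }
  }
  structure(list(spike_time = sol$spike_time[1L], causal_indices = causal,
                 coeffs = coeffs, tau_ratio = constants$tau_ratio),
            class = "causal_solution")
}

#' @export
print.causal_solution <- function(x, ...) {
  if (is.finite(x$spike_time)) {
    cat(sprintf("first spike at T = %.6g (causal inputs: %s)\n",
                x$spike_time, paste(x$causal_indices, collapse = ", ")))
  } else {
    cat("silent (no threshold crossing)\n")
  }
  invisible(x)
}

# Vectorized first-spike solve over rows.
#
# arr, W: M x N matrices of arrival times and weights (one row per
# independent neuron instance). Returns spike times and everything the
# backward pass needs: per-row accepted causal size k, sorted arrival
# times/weights, the sorted->original column map, and the accepted
# coefficients (a1, a2/sqrtD for ratio 2; a1, b, w0 for ratio 1).
solve_arrivals <- function(arr, W, constants) {
  M <- nrow(arr); N <- ncol(arr)
  ts <- constants$tau_s
  thr <- constants$threshold
  ratio2 <- constants$tau_ratio == 2L

  # stable row-wise sort by (time, input index) via one global order
  ri <- rep(seq_len(M), times = N)
  ci <- rep(seq_len(N), each = M)
  o <- order(ri, as.vector(arr), ci, method = "radix")
  St <- matrix(arr[o], M, N, byrow = TRUE)          # sorted arrival times
  Sc <- matrix(ci[o], M, N, byrow = TRUE)           # original column index
  Sw <- matrix(W[o],  M, N, byrow = TRUE)           # weights, same order

  usable <- is.finite(St) & (St / ts) < .EXP_TIME_CAP
  Tz <- ifelse(usable, St, 0)                        # safe exponent input
  Wz <- ifelse(usable, Sw, 0)

  UT <- matrix(0, N, N); UT[upper.tri(UT, diag = TRUE)] <- 1

  if (ratio2) {
    E1 <- Wz * exp(Tz / ts)
    E2 <- Wz * exp(Tz / (2 * ts))
    a1k <- 2 * (E1 %*% UT)
    a2k <- 2 * (E2 %*% UT)
    D <- a2k^2 - 4 * a1k * thr
    eps <- 1e-12 * pmax(a2k^2, abs(4 * a1k * thr))
    D[D < 0 & D >= -eps] <- 0
    sq <- sqrt(pmax(D, 0))
    den <- a2k + sq
    valid <- a1k > 0 & D >= 0 & den > 0
    Tk <- matrix(SILENT, M, N)
    Tk[valid] <- 2 * ts * (log(2 * a1k[valid]) - log(den[valid]))
  } else {
    E1 <- Wz * exp(Tz / ts)
    Eb <- Wz * (Tz / ts) * exp(Tz / ts)
    a1k <- E1 %*% UT
    bk  <- Eb %*% UT
    valid <- a1k > 0
    larg <- matrix(Inf, M, N)
    larg[valid] <- log(thr / a1k[valid]) + bk[valid] / a1k[valid]
    valid <- valid & larg <= -1 + 1e-12
    w0k <- matrix(NA_real_, M, N)
    w0k[valid] <- lambert_w0(-exp(pmin(larg[valid], -1)))
    Tk <- matrix(SILENT, M, N)
    Tk[valid] <- ts * (bk[valid] / a1k[valid] - w0k[valid])
  }

  # candidate acceptance: t_(k) <= T < t_(k+1), with relative tolerance at
  # the lower boundary; non-usable (silent) arrivals can never be causal.
  lower <- St - 1e-12 * pmax(1, abs(St))
  upper <- cbind(St[, -1, drop = FALSE], rep(SILENT, M))
  ok <- valid & usable & (Tk >= lower) & (Tk < upper)

  has <- rowSums(ok) > 0
  pick <- max.col(ok * rep(N:1, each = M), ties.method = "first")
  idx <- cbind(seq_len(M), pick)
  Tout <- Tk[idx]
  Tout[!has] <- SILENT
  k <- ifelse(has, pick, 0L)

  out <- list(spike_time = Tout, k = k, sort_col = Sc, sorted_t = St,
              sorted_w = Sw, usable = usable,
              a1 = ifelse(has, a1k[idx], NA_real_))
  if (ratio2) {
    out$a2 <- ifelse(has, a2k[idx], NA_real_)
    out$sqrtD <- ifelse(has, sq[idx], NA_real_)
  } else {
    out$b <- ifelse(has, bk[idx], NA_real_)
    out$w0 <- ifelse(has, w0k[idx], NA_real_)
  }
  out
}

#' Forward pass of one neuron layer
#'
#' Applies [first_spike()] independently to every postsynaptic neuron, for a
#' single sample or a batch. The returned cache retains exactly what the
#' backward pass consumes -- sorted arrival times, weights, accepted causal
#' sizes and crossing coefficients -- and nothing else (no membrane traces).
#'
#' @param input_spikes Numeric vector of length `pre` (one sample) or a
#'   `B x pre` matrix (batch of samples); `Inf` marks silent inputs.
#' @param weight_matrix `pre x post` weight matrix.
#' @param constants A [neuron_constants()] object.
#' @param arrivals Optional pre-expanded arrival structure from
#'   [delay_forward()]; when supplied, `input_spikes` is ignored.
#' @return A list with `times` (length-`post` vector or `B x post` matrix of
#'   output spike times) and `cache` (for [neuron_backward()]).
#' @export
layer_forward <- function(input_spikes, weight_matrix, constants,
                          arrivals = NULL) {
  if (is.null(arrivals)) {
    tm <- if (is.matrix(input_spikes)) input_spikes else
      matrix(input_spikes, nrow = 1L)
    arrivals <- list(arr = tm, B = nrow(tm), N = ncol(tm), shared = TRUE)
  }
  N <- arrivals$N
  if (nrow(weight_matrix) != N)
    stop(sprintf("weight matrix has %d rows but layer receives %d inputs",
                 nrow(weight_matrix), N), call. = FALSE)
  P <- ncol(weight_matrix)
  B <- arrivals$B
  if (!is.null(arrivals$P) && arrivals$P != P)
    stop("arrival structure post-dimension does not match weight matrix",
         call. = FALSE)

  # expand to one row per (sample, postsynaptic neuron): m = (p-1)*B + b
  arr <- if (arrivals$shared) arrivals$arr[rep(seq_len(B), P), , drop = FALSE]
         else arrivals$arr
  # weight column p repeated B times, matching the m = (p-1)*B + b order
  Wexp <- t(weight_matrix[, rep(seq_len(P), each = B), drop = FALSE])

  sol <- solve_arrivals(arr, Wexp, constants)
  times <- matrix(sol$spike_time, nrow = B, ncol = P)
  if (B == 1L && !is.matrix(input_spikes) && is.null(arrivals$P))
    times_out <- drop(times)
  else times_out <- times
  cache <- list(sol = sol, B = B, P = P, N = N, constants = constants,
                shared = arrivals$shared)
  list(times = times_out, cache = cache)
}
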