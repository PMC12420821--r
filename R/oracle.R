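#' Analytic membrane potential (kernel sum)
#'
#' The normalized membrane potential of the single-spike LIF model is an
#' explicit sum of per-input PSP kernels,
#' \eqn{u(t) = \sum_i w_i\,\kappa(t - t_i)} with
#' \eqn{\kappa(\Delta) = 2(e^{-\Delta/2\tau_s} - e^{-\Delta/\tau_s})} for
#' `tau_ratio = 2` and the alpha kernel
#' \eqn{\kappa(\Delta) = (\Delta/\tau_s) e^{-\Delta/\tau_s}} for
#' `tau_ratio = 1` (both zero for \eqn{\Delta < 0}). This closed membrane
#' solution is independent of the spike-time formulas and serves as the
#' ground truth they are tested against; it is itself validated against
#' direct numerical integration of the membrane ODE.
#'
#' @param t Numeric vector of evaluation times.
#' @param arrival_times,weights Input spikes (silent `Inf` entries are
#'   ignored).
#' @param constants A [neuron_constants()] object.
#' @return Membrane values at `t` (relative to the leak potential).
#' @export
membrane_potential <- function(t, arrival_times, weights, constants) {
  ts <- constants$tau_s
  fin <- is.finite(arrival_times)
  ti <- arrival_times[fin]; wi <- weights[fin]
  if (length(ti) == 0L) return(rep(constants$leak * 0, length(t)))
  dt <- outer(t, ti, "-")
  k <- if (constants$tau_ratio == 2L) {
    ifelse(dt > 0, 2 * (exp(-dt / (2 * ts)) - exp(-dt / ts)), 0)
  } else {
    ifelse(dt > 0, (dt / ts) * exp(-dt / ts), 0)
  }
  as.vector(k %*% wi)
}

#' Oracle first-spike time by bracketed root-finding
#'
#' Independent ground truth for [first_spike()]: scans the analytic
#' membrane trajectory (which is exact between input events) on a fine
#' grid within each inter-event interval, brackets the first upward
#' threshold crossing, and refines it with [stats::uniroot()] to
#' `1e-12` absolute tolerance. Grid spacing is bounded by `tau_s / 50`, so
#' only crossings within a vanishing band of tangency can be missed.
#'
#' @param arrival_times,weights Input spikes.
#' @param constants A [neuron_constants()] object.
#' @param horizon Scan end; default latest finite arrival + `10 tau_m`.
#' @return First crossing time, or `Inf` if the membrane never reaches
#'   threshold.
#' @export
oracle_first_spike <- function(arrival_times, weights, constants,
                               horizon = NULL) {
  fin <- is.finite(arrival_times)
  if (!any(fin)) return(SILENT)
  ev <- sort(unique(arrival_times[fin]))
  if (is.null(horizon)) horizon <- max(ev) + 10 * constants$tau_m
  knots <- unique(c(ev, horizon))
  u <- function(t) membrane_potential(t, arrival_times, weights, constants)
  thr <- constants$threshold
  for (j in seq_len(length(knots))) {
    a <- knots[j]
    b <- if (j < length(knots)) knots[j + 1L] else horizon
    if (b <= a) next
    ng <- max(16L, ceiling((b - a) / (constants$tau_s / 50)))
    g <- seq(a, b, length.out = ng + 1L)
    ug <- u(g)
    i <- which(ug >= thr)[1L]
    if (!is.na(i)) {
      if (i == 1L) return(a)  # crossing exactly at the event time
      root <- stats::uniroot(function(t) u(t) - thr, c(g[i - 1L], g[i]),
                             tol = 1e-12)$root
      return(root)
    }
  }
  SILENT
}

#' Numerically integrate the membrane ODE
#'
#' Direct high-accuracy integration of the membrane equation
#' \eqn{\tau_m \dot u = (E_\ell - u) + (\tau_m/\tau_s) I_s(t)/g_\ell} with
#' the exponential synaptic current \eqn{I_s(t) = \sum_i \Theta(t - t_i)
#' w_i e^{-(t-t_i)/\tau_s}} (the synaptic coupling is normalized by
#' \eqn{\tau_m/\tau_s} so that the PSP kernels above solve the equation
#' exactly). Used to validate the analytic kernel sum; the reported
#' crossing is refined by root-finding on the kernel-sum expression, which
#' is exact between events, so no integrator bias enters spike-time
#' comparisons.
#'
#' @param arrival_times,weights Input spikes.
#' @param constants A [neuron_constants()] object.
#' @param horizon Integration end; default latest arrival + `10 tau_m`.
#' @param n Number of grid points of the returned trace.
#' @return A list with `time`, `u` (the integrated trace), `u_kernel` (the
#'   analytic kernel sum on the same grid), `max_dev` (their maximum
#'   absolute difference) and `crossing` (first upward threshold crossing,
#'   or `Inf`).
#' @export
integrate_membrane <- function(arrival_times, weights, constants,
                               horizon = NULL, n = 2001L) {
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("integrate_membrane requires the deSolve package", call. = FALSE)
  fin <- is.finite(arrival_times)
  ti <- arrival_times[fin]; wi <- weights[fin]
  t0 <- if (length(ti)) min(ti, 0) else 0
  if (is.null(horizon))
    horizon <- (if (length(ti)) max(ti) else 0) + 10 * constants$tau_m
  ts <- constants$tau_s; tm <- constants$tau_m
  Is <- function(t) if (length(ti))
    sum(ifelse(t > ti, wi * exp(-(t - ti) / ts), 0)) else 0
  rhs <- function(t, y, parms)
    list((constants$leak - y[1] + (tm / ts) * Is(t)) / tm)
  grid <- sort(unique(c(seq(t0, horizon, length.out = n), ti)))
  out <- deSolve::ode(c(u = constants$leak), grid, rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  uk <- constants$leak +
    membrane_potential(out[, 1], arrival_times, weights, constants)
  list(time = out[, 1], u = out[, 2], u_kernel = uk,
       max_dev = max(abs(out[, 2] - uk)),
       crossing = oracle_first_spike(arrival_times, weights, constants,
                                     horizon = horizon))
}

#' Central finite-difference gradient
#'
#' Test utility: central differences per coordinate,
#' \eqn{(f(x + h e_i) - f(x - h e_i)) / (2h)}.
#'
#' @param f Scalar function of a numeric vector.
#' @param x Evaluation point.
#' @param h Step size.
#' @return Numeric gradient estimate, same length as `x`.
#' @export
finite_diff <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
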