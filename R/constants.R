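#' Neuron constants for the closed-form LIF model
#'
#' Bundles the parameters of a leaky integrate-and-fire neuron with
#' exponential current-based synapses for which the first-spike time has a
#' closed form. Internally the model is normalized: the leak conductance and
#' threshold enter only through their product (`threshold`), the leak
#' potential is the voltage origin, and times are measured in units of
#' `tau_s`. Only the two ratios `tau_m/tau_s` in {1, 2} admit an analytic
#' first-spike time; all neurons fire at most once (infinite refractory
#' period), so no reset parameters are housed here.
#'
#' @param tau_s Synaptic time constant (the time unit). Must be positive.
#' @param tau_ratio Integer membrane-to-synaptic time-constant ratio,
#'   `tau_m = tau_ratio * tau_s`. Either 1 (alpha-kernel PSP, Lambert-W
#'   spike time) or 2 (double-exponential PSP, quadratic spike time).
#' @param threshold Product of leak conductance and voltage threshold in
#'   normalized units. Must be positive.
#' @param leak Leak (resting) potential; the voltage origin. Default 0.
#' @return An object of class `neuron_constants`.
#' @examples
#' nc <- neuron_constants(tau_s = 1, tau_ratio = 2)
#' @export
neuron_constants <- function(tau_s = 1, tau_ratio = 2, threshold = 1,
                             leak = 0) {
  stopifnot(is.numeric(tau_s), length(tau_s) == 1L, tau_s > 0,
            is.numeric(threshold), length(threshold) == 1L, threshold > 0,
            length(tau_ratio) == 1L, tau_ratio %in% c(1, 2))
  structure(
    list(tau_s = as.numeric(tau_s), tau_ratio = as.integer(tau_ratio),
         threshold = as.numeric(threshold), leak = as.numeric(leak),
         tau_m = as.numeric(tau_ratio) * as.numeric(tau_s)),
    class = "neuron_constants")
}

#' @export
print.neuron_constants <- function(x, ...) {
  cat(sprintf(
    "LIF constants: tau_s = %g, tau_m = %g (ratio %d), g_l*theta = %g, E_l = %g\n",
    x$tau_s, x$tau_m, x$tau_ratio, x$threshold, x$leak))
  invisible(x)
}

# Silent-neuron sentinel: IEEE +Inf, so that ordering-based readout
# (earliest spike wins) works unchanged.
SILENT <- Inf

#' Test for the silent-neuron sentinel
#'
#' Silent neurons (no threshold crossing) are represented by `+Inf` spike
#' times so that time ordering and earliest-spike readout need no special
#' casing.
#'
#' @param times Numeric vector or matrix of spike times.
#' @return Logical of the same shape, `TRUE` where silent.
#' @export
is_silent <- function(times) !is.finite(times)

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arrivals later than this (in units of tau_s, relative to 0) are treated as
# never-arriving to keep exp(t/tau_s) terms inside double range. Task spike
# times live within a few tau_s, so the cap is far from any physical regime.
.EXP_TIME_CAP <- 500
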