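# Random single-neuron instances used by the oracle-equivalence and
# gradient-check suites: n inputs in [1,10], weights in [-2,4], times in
# [0, 3 tau_s].
random_instance <- function() {
  n <- sample(1:10, 1)
  list(w = runif(n, -2, 4), t = runif(n, 0, 3))
}

# A small network whose neurons all fire for the given batch (gradient
# checks need smooth points away from causal-set boundaries).
active_network <- function(sizes, kind, X, lambda = 1, max_tries = 20) {
  for (i in seq_len(max_tries)) {
    m <- build_network(sizes, delay_kind = kind, lambda_bound = lambda,
                       init_mean_scale = 6, init_sd_scale = 1.2)
    fw <- network_forward(X, m)
    if (all(is.finite(unlist(fw$layers)))) return(m)
  }
  NULL
}

# Dimensionless distance of a solved neuron from a grazing (tangent)
# crossing: the discriminant margin (ratio 2) or 1 + W0 (ratio 1). Near
# zero the spike-time derivative is unbounded and central differences are
# dominated by truncation, so gradient checks exclude such points.
tangency_margin <- function(fs, nc) {
  co <- fs$coeffs
  if (nc$tau_ratio == 2) {
    D <- co$a2^2 - 4 * co$a1 * nc$threshold
    sqrt(max(D, 0)) / abs(co$a2)
  } else {
    larg <- log(nc$threshold / co$a1) + co$b / co$a1
    1 + lambert_w0(-exp(min(larg, -1)))
  }
}
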