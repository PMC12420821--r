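test_that("causal coefficients are exponential sums over the causal set", {
  nc <- neuron_constants(tau_ratio = 2)
  co <- causal_coefficients(3, 0, 1, nc)
  expect_equal(co$a1, 6)
  expect_equal(co$a2, 6)

  co2 <- causal_coefficients(c(1.5, 3), c(0, 1), 1:2, nc)
  expect_equal(co2$a1, 2 * (1.5 + 3 * exp(1)))
  expect_equal(co2$a2, 2 * (1.5 + 3 * exp(0.5)))

  # zero-weight inputs contribute nothing
  co3 <- causal_coefficients(c(2, 0), c(0.3, 1.7), 1:2, nc)
  co4 <- causal_coefficients(2, 0.3, 1, nc)
  expect_equal(co3, co4)

  expect_error(causal_coefficients(1, 0, integer(), nc), "causal")
})

test_that("quadratic spike time matches its worked cases", {
  nc <- neuron_constants(tau_ratio = 2)
  # crossing of a single w = 3 input at t = 0 (ODE oracle value)
  expect_equal(spike_time_ratio2(list(a1 = 6, a2 = 6), nc), 0.4748016,
               tolerance = 1e-6)
  # tangent case: PSP maximum of a w = 2 input exactly reaches threshold
  expect_equal(spike_time_ratio2(list(a1 = 4, a2 = 4), nc), 2 * log(2))
  # subthreshold (w = 1, kernel max 0.5 < 1): silent, not an error
  expect_identical(spike_time_ratio2(list(a1 = 2, a2 = 2), nc), Inf)
  expect_identical(spike_time_ratio2(list(a1 = -1, a2 = 3), nc), Inf)
})

test_that("principal-branch Lambert W satisfies its defining equation", {
  xs <- c(-exp(-1), -exp(-1) + 1e-12, seq(-0.36, -0.01, by = 0.007),
          -1e-6, -1e-12,
          -0.36684239321722001)  # argument on which pracma's solver stalls
  w <- lambert_w0(xs)
  expect_lt(max(abs(w * exp(w) - xs)), 1e-15)
  expect_true(all(w >= -1 & w <= 0))
  expect_equal(lambert_w0(-exp(-1)), -1)
  # independent cross-check on arguments away from the branch point
  safe <- xs > -0.35
  expect_equal(w[safe], vapply(xs[safe], pracma::lambertWp, numeric(1)),
               tolerance = 1e-12)
  expect_error(lambert_w0(-0.5), "below")
})

test_that("Lambert-W spike time agrees with the membrane oracle", {
  nc <- neuron_constants(tau_ratio = 1)
  for (w in c(3, 4, 6)) {
    co <- causal_coefficients(w, 0, 1, nc)
    T1 <- spike_time_ratio1(co, nc)
    expect_equal(T1, oracle_first_spike(0, w, nc), tolerance = 1e-9)
  }
  # critical weight: alpha-kernel maximum is w/e, threshold 1 => w_c = e
  expect_identical(
    spike_time_ratio1(causal_coefficients(exp(1) * 0.999, 0, 1, nc), nc),
    Inf)
  expect_true(is.finite(
    spike_time_ratio1(causal_coefficients(exp(1) * 1.001, 0, 1, nc), nc)))
})

test_that("homogeneity: scaling weights and threshold leaves T unchanged", {
  for (ratio in 1:2) {
    set.seed(42 + ratio)
    for (i in 1:20) {
      n <- sample(1:6, 1)
      w <- runif(n, 0.5, 4); t <- runif(n, 0, 2)
      c_scale <- runif(1, 0.2, 5)
      nc <- neuron_constants(tau_ratio = ratio)
      ncs <- neuron_constants(tau_ratio = ratio, threshold = c_scale)
      T1 <- first_spike(t, w, nc)$spike_time
      T2 <- first_spike(t, c_scale * w, ncs)$spike_time
      expect_equal(T1, T2, tolerance = 1e-12)
    }
  }
})

test_that("first_spike searches causal sets event by event", {
  nc <- neuron_constants(tau_ratio = 2)
  # inhibitory input arriving after the spike is excluded
  fs <- first_spike(c(0, 1), c(3, -5), nc)
  expect_equal(fs$spike_time, 0.4748016, tolerance = 1e-6)
  expect_identical(fs$causal_indices, 1L)

  # subthreshold alone, crossing only once the second input arrives
  # (oracle-computed crossing: 1.096104)
  fs2 <- first_spike(c(0, 1), c(1.5, 3), nc)
  expect_equal(fs2$spike_time, 1.096104, tolerance = 1e-6)
  expect_identical(fs2$causal_indices, c(1L, 2L))

  # all-silent inputs give the silent solution
  fs3 <- first_spike(c(Inf, Inf), c(2, 2), nc)
  expect_identical(fs3$spike_time, Inf)
  expect_length(fs3$causal_indices, 0)

  expect_error(first_spike(c(0, NaN), c(1, 1), nc), "NaN")
})

test_that("returned causal set is a fixed point of the solve", {
  for (ratio in 1:2) {
    nc <- neuron_constants(tau_ratio = ratio)
    set.seed(100 + ratio)
    n_checked <- 0
    for (i in 1:50) {
      inst <- random_instance()
      fs <- first_spike(inst$t, inst$w, nc)
      if (!is.finite(fs$spike_time)) next
      n_checked <- n_checked + 1
      ci <- which(inst$t < fs$spike_time)
      expect_setequal(fs$causal_indices, ci)
      fs2 <- first_spike(inst$t[ci], inst$w[ci], nc)
      expect_equal(fs2$spike_time, fs$spike_time, tolerance = 1e-9)
    }
    expect_gt(n_checked, 10)
  }
})

test_that("shift equivariance holds exactly", {
  for (ratio in 1:2) {
    nc <- neuron_constants(tau_ratio = ratio)
    set.seed(200 + ratio)
    for (i in 1:25) {
      inst <- random_instance()
      delta <- runif(1, -2, 4)
      T0 <- first_spike(inst$t, inst$w, nc)$spike_time
      T1 <- first_spike(inst$t + delta, inst$w, nc)$spike_time
      if (is.finite(T0)) {
        expect_equal(T1, T0 + delta, tolerance = 1e-9)
      } else {
        expect_identical(T1, Inf)
      }
    }
  }
})

test_that("layer_forward reduces to first_spike and respects permutations", {
  nc <- neuron_constants(tau_ratio = 2)
  set.seed(3)
  w <- runif(3, 0, 2); x <- runif(3, 0, 1)
  lf <- layer_forward(x, matrix(w, 3, 1), nc)
  expect_equal(lf$times, first_spike(x, w, nc)$spike_time)

  W <- matrix(rnorm(3 * 5, 1, 0.5), 3, 5)
  perm <- sample(5)
  t_full <- layer_forward(x, W, nc)$times
  t_perm <- layer_forward(x, W[, perm], nc)$times
  expect_equal(t_perm, t_full[perm])

  expect_error(layer_forward(x, matrix(1, 4, 2), nc), "inputs")
})

test_that("every finite layer output exceeds its earliest causal arrival", {
  nc <- neuron_constants(tau_ratio = 2)
  set.seed(4)
  X <- matrix(runif(20 * 4, 0, 2), 20, 4)
  W <- matrix(rnorm(4 * 30, 1.2, 0.6), 4, 30)
  out <- layer_forward(X, W, nc)$times
  fin <- is.finite(out)
  expect_true(any(fin))
  expect_true(all(out[fin] > apply(X, 1, min)[row(out)[fin]]))
})
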