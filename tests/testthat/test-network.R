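test_that("delay forward adds bounded delays and preserves silence", {
  p <- delay_params("none", 2, 3)
  t <- matrix(c(1, 2), 1, 2)
  expect_equal(delay_forward(t, p)$arr, t)

  pa <- delay_params("axonal", 2, 3, lambda_bound = 1,
                     theta = c(0, 0))  # sigmoid(0) = 1/2, delay lambda/2
  a <- delay_forward(matrix(c(1, Inf), 1, 2), pa)
  expect_equal(a$arr[1, 1], 1.5, tolerance = 1e-12)
  expect_identical(a$arr[1, 2], Inf)  # silent stays silent

  # synaptic: componentwise addition, arrivals per (pre, post) pair
  d <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  frac <- pmin(pmax(d / 1, 1e-9), 1 - 1e-9)
  ps <- delay_params("synaptic", 2, 2, 1, theta = log(frac / (1 - frac)))
  s <- delay_forward(matrix(c(1, 2), 1, 2), ps)
  expect_false(s$shared)
  # block p = 1 then p = 2; columns are presynaptic index
  expect_equal(s$arr, rbind(c(1.1, 2.3), c(1.2, 2.4)), tolerance = 1e-6)
})

test_that("effective delays stay inside (0, lambda)", {
  set.seed(21)
  for (kind in c("axonal", "dendritic", "synaptic")) {
    p <- delay_params(kind, 4, 5, lambda_bound = 2.5,
                      theta = rnorm(if (kind == "synaptic") 20 else
                                      if (kind == "axonal") 4 else 5, 0, 5))
    d <- effective_delays(p)
    expect_true(all(d > 0 & d < 2.5))
  }
})

test_that("zero-delay model behaves like a delay-free model", {
  set.seed(22)
  m <- build_network(c(4, 5, 3), delay_kind = "none")
  ms <- m
  # synaptic delays forced to (numerically) zero
  ms$delays <- list(delay_params("synaptic", 4, 5, 1,
                                 theta = rep(-Inf, 20)),
                    delay_params("synaptic", 5, 3, 1,
                                 theta = rep(-Inf, 15)))
  ms$delay_kind <- "synaptic"
  X <- matrix(runif(6 * 4, 0, 2), 6, 4)
  expect_equal(network_forward(X, ms)$output, network_forward(X, m)$output)
})

test_that("uniform dendritic delay equals axonal delay on the output", {
  # time-shift invariance of the neuron makes the two placements redundant
  set.seed(23)
  m <- build_network(c(3, 4, 2), delay_kind = "none")
  X <- matrix(runif(5 * 3, 0, 1.5), 5, 3)
  d0 <- 0.37
  frac <- d0 / 1
  th <- log(frac / (1 - frac))

  md <- m
  md$delays[[1]] <- delay_params("dendritic", 3, 4, 1, theta = rep(th, 4))
  out_d <- network_forward(X, md)$output

  base <- network_forward(X, m)
  hidden_shifted <- base$layers[[1]] + d0   # axonal delay after the neuron
  out_a <- layer_forward(hidden_shifted, m$weights[[2]], m$constants)$times
  expect_equal(out_d, out_a, tolerance = 1e-9)

  # and the loss gradient w.r.t. that shared delay is identical
  y <- sample(1:2, 5, TRUE)
  lg <- loss_delta_mse_grad(out_d, y, 0.2)
  fwd <- network_forward(X, md)
  bwd <- network_backward(lg$grad, fwd$caches, md)
  dd_dend <- sum(bwd$dtheta[[1]]) / reparam_grad(th, 1)

  ma <- m
  ma$delays[[2]] <- delay_params("axonal", 4, 2, 1, theta = rep(th, 4))
  # dendritic on block 1 shifts each hidden neuron's inputs; the equivalent
  # axonal delay sits on the hidden neurons' outputs (block 2 presynaptic)
  fwa <- network_forward(X, ma)
  expect_equal(fwa$output, out_d, tolerance = 1e-9)
  bwa <- network_backward(loss_delta_mse_grad(fwa$output, y, 0.2)$grad,
                          fwa$caches, ma)
  dd_axo <- sum(bwa$dtheta[[2]]) / reparam_grad(th, 1)
  expect_equal(dd_dend, dd_axo, tolerance = 1e-8)
})

test_that("network forward composes per-neuron solves on delayed arrivals", {
  set.seed(24)
  m <- build_network(c(4, 30, 3), delay_kind = "synaptic", lambda_bound = 1)
  x <- runif(4, 0, 2)
  fw <- network_forward(x, m)
  d1 <- effective_delays(m$delays[[1]])
  manual_hidden <- vapply(1:30, function(j)
    first_spike(x + d1[, j], m$weights[[1]][, j], m$constants)$spike_time,
    numeric(1))
  expect_equal(as.vector(fw$layers[[1]]), manual_hidden, tolerance = 1e-12)
  d2 <- effective_delays(m$delays[[2]])
  manual_out <- vapply(1:3, function(j)
    first_spike(manual_hidden + d2[, j], m$weights[[2]][, j],
                m$constants)$spike_time, numeric(1))
  expect_equal(as.vector(fw$output), manual_out, tolerance = 1e-12)
})

test_that("parameter counts follow the delay taxonomy shapes", {
  m <- build_network(c(4, 30, 3), delay_kind = "synaptic")
  pc <- count_parameters(m)
  expect_equal(pc$weights, 210)
  expect_equal(pc$delays, 210)
  expect_equal(pc$total, 420)
  expect_equal(count_parameters(
    build_network(c(4, 30, 3), delay_kind = "axonal"))$delays, 34)
  expect_equal(count_parameters(
    build_network(c(4, 30, 3), delay_kind = "dendritic"))$delays, 33)
  expect_equal(count_parameters(
    build_network(c(4, 30, 3), delay_kind = "none"))$delays, 0)

  # property over random topologies
  set.seed(25)
  for (i in 1:10) {
    sizes <- sample(2:12, sample(3:5, 1), replace = TRUE)
    pre <- sizes[-length(sizes)]; post <- sizes[-1]
    for (kind in c("none", "axonal", "dendritic", "synaptic")) {
      m <- build_network(sizes, delay_kind = kind)
      pc <- count_parameters(m)
      expect_equal(pc$weights, sum(pre * post))
      expect_equal(pc$delays, switch(kind, none = 0, axonal = sum(pre),
                                     dendritic = sum(post),
                                     synaptic = sum(pre * post)))
    }
  }
})

test_that("end-to-end gradients match finite differences on small nets", {
  set.seed(26)
  n_checked <- 0
  for (kind in c("none", "axonal", "dendritic", "synaptic")) {
    X <- matrix(runif(3 * 4, 0, 2), 3, 4)
    y <- sample(1:3, 3, replace = TRUE)
    m <- active_network(c(4, 8, 3), kind, X)
    if (is.null(m)) next
    fw <- network_forward(X, m)
    lg <- loss_delta_mse_grad(fw$output, y, 0.2)
    bw <- network_backward(lg$grad, fw$caches, m)
    lossfn <- function(m2) loss_delta_mse(network_forward(X, m2)$output,
                                          y, 0.2)
    for (l in 1:2) {
      fd <- finite_diff(function(v) {
        m2 <- m; m2$weights[[l]][] <- v; lossfn(m2)
      }, as.vector(m$weights[[l]]))
      expect_lt(max(abs(fd - as.vector(bw$dW[[l]])) / pmax(abs(fd), 1e-3)),
                1e-4)
      if (!is.null(m$delays[[l]]$theta)) {
        fd2 <- finite_diff(function(v) {
          m2 <- m; m2$delays[[l]]$theta[] <- v; lossfn(m2)
        }, as.vector(m$delays[[l]]$theta))
        expect_lt(max(abs(fd2 - as.vector(bw$dtheta[[l]])) /
                        pmax(abs(fd2), 1e-3)), 1e-4)
      }
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 3)
  # no delay gradients for kind = none
  m0 <- build_network(c(4, 5, 3), delay_kind = "none")
  fw0 <- network_forward(matrix(runif(8, 0, 2), 2, 4), m0)
  bw0 <- network_backward(matrix(0.1, 2, 3), fw0$caches, m0)
  expect_true(all(vapply(bw0$dtheta, is.null, logical(1))))
})

test_that("model JSON serialization round-trips exactly", {
  set.seed(27)
  for (kind in c("none", "synaptic")) {
    m <- build_network(c(4, 7, 3), delay_kind = kind, lambda_bound = 1.5)
    js <- model_to_json(m)
    m2 <- model_from_json(js)
    expect_identical(m2$sizes, m$sizes)
    expect_equal(m2$weights, m$weights, tolerance = 0)
    for (l in 1:2)
      expect_equal(m2$delays[[l]]$theta, m$delays[[l]]$theta, tolerance = 0)
    X <- matrix(runif(8, 0, 2), 2, 4)
    expect_identical(network_forward(X, m2)$output,
                     network_forward(X, m)$output)
  }
})
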