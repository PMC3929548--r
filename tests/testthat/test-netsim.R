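test_that("random network generation respects density, diagonal and seed", {
  net0 <- generate_random_network(2, density = 0, seed = 1)
  expect_equal(sum(net0$adjacency), 0)

  net <- generate_random_network(100, density = 0.05, seed = 42)
  expect_equal(dim(net$adjacency), c(100, 100))
  expect_true(all(diag(net$adjacency) == 0))
  # observed edge count within the binomial 99% interval around 0.05 * 9900
  ci <- qbinom(c(0.005, 0.995), 9900, 0.05)
  expect_gte(sum(net$adjacency), ci[1])
  expect_lte(sum(net$adjacency), ci[2])

  net2 <- generate_random_network(100, density = 0.05, seed = 42)
  expect_identical(net$adjacency, net2$adjacency)

  expect_error(generate_random_network(1, density = 0.5), "two neurons")
  expect_error(generate_random_network(10, density = 1.5), "density")
  expect_error(network_spec(matrix(1, 2, 2)), "autapses")
})

test_that("Poisson trains have the right statistics and copy semantics", {
  d0 <- drive_spec(rate = 0, strength = 0.01)
  tr0 <- sample_poisson_trains(d0, 3, 1000, seed = 1)
  expect_true(all(lengths(tr0$times) == 0))

  # rate * duration = 1000: counts within 3 sqrt(1000) for a batch of seeds
  d <- drive_spec(rate = 1, strength = 0.01)
  counts <- vapply(1:20, function(s)
    length(sample_poisson_trains(d, 1, 1000, seed = s)$times[[1]]), 1L)
  expect_true(mean(abs(counts - 1000) <= 3 * sqrt(1000)) >= 0.95)

  # the shared train appears identically in every targeted neuron's list
  dc <- drive_spec(rate = 0.5, strength = 0.01, common_rate = 0.2,
                   common_strength = 0.03)
  tr <- sample_poisson_trains(dc, 3, 5000, seed = 7)
  for (i in 1:3) {
    got <- tr$times[[i]][tr$strengths[[i]] == 0.03]
    expect_equal(got, tr$common)
  }

  # substreams: adding a neuron leaves existing trains unchanged
  a <- sample_poisson_trains(d, 2, 1000, seed = 3)
  b <- sample_poisson_trains(d, 3, 1000, seed = 3)
  expect_identical(a$times[[1]], b$times[[1]])
  expect_identical(a$times[[2]], b$times[[2]])
})

test_that("common input fraction follows the rate-fraction convention", {
  expect_equal(common_input_fraction(drive_spec(rate = 10, common_rate = 0)), 0)
  expect_equal(common_input_fraction(drive_spec(rate = 0, common_rate = 5)), 1)
  expect_equal(common_input_fraction(drive_spec(rate = 3, common_rate = 1)), 0.25)
  expect_error(common_input_fraction(drive_spec(rate = 0, common_rate = 0)),
               "undefined")
})

test_that("a quiescent neuron stays at its equilibrium and never spikes", {
  net <- network_spec(matrix(0, 1, 1), S_ee = 0)
  p <- neuron_params()
  rec <- simulate_network(net, p, drive_spec(rate = 0, strength = 0),
                          duration = 1000, seed = 1,
                          v0 = p$E_L)
  expect_equal(length(rec$spikes[[1]]), 0)
  expect_true(all(abs(rec$voltages[, 1] - p$E_L) < 1e-12))
})

test_that("subthreshold response to one input spike matches a fine-step oracle", {
  skip_if_not_installed("deSolve")
  p <- neuron_params()
  f <- 0.05
  t0 <- 20.025  # deliberately off the integration grid
  net <- network_spec(matrix(0, 1, 1))
  trains <- list(times = list(t0), strengths = list(f))
  rec <- simulate_network(net, p, trains, duration = 100, dt = 0.01, fs = 1,
                          seed = 1, v0 = 0.2)
  # oracle: adaptive high-accuracy ODE integration of the same event sequence
  rhs <- function(t, y, parms) {
    G <- if (t >= t0) f * exp(-(t - t0) / p$tau_E) else 0
    list(-p$g_L * (y - p$E_L) - G * (y - p$E_E))
  }
  fine <- deSolve::lsoda(c(V = 0.2), seq(0, 100, by = 0.01), rhs, NULL,
                         rtol = 1e-12, atol = 1e-12)
  vfine <- fine[, 2]
  # window-average the oracle by the same trapezoid rule on the step grid
  ref <- vapply(1:100, function(w) {
    seg <- vfine[((w - 1) * 100 + 1):(w * 100 + 1)]
    mean(head(seg, -1) + tail(seg, -1)) / 2
  }, 1)
  expect_lt(max(abs(rec$voltages[, 1] - ref)), 1e-6)
  expect_equal(length(rec$spikes[[1]]), 0)
})

test_that("interspike intervals respect the refractory period", {
  rec <- sim_two_neuron(rate = 1.0, duration = 20e3, seed = 5)
  for (i in 1:2) {
    isi <- diff(rec$spikes[[i]])
    expect_true(all(isi >= neuron_params()$tau_ref - 1e-9))
  }
})

test_that("firing becomes more regular as the drive rate grows", {
  cv <- function(rate, seed) {
    rec <- sim_two_neuron(rate = rate, duration = 30e3, seed = seed)
    isi <- diff(rec$spikes[[1]])
    sd(isi) / mean(isi)
  }
  expect_gt(cv(0.25, 2), cv(1.5, 2))
})

test_that("uncoupled neurons have seed-stable independent statistics", {
  # with all couplings zero, per-neuron statistics do not depend on the
  # presence of other neurons (drive substreams are per-neuron)
  net1 <- network_spec(matrix(0, 1, 1))
  net3 <- network_spec(matrix(0, 3, 3))
  d <- drive_spec(rate = 0.5, strength = 0.02)
  r1 <- simulate_network(net1, drive = d, duration = 10e3, seed = 11)
  r3 <- simulate_network(net3, drive = d, duration = 10e3, seed = 11)
  expect_equal(r1$spikes[[1]], r3$spikes[[1]])
  expect_equal(r1$voltages[, 1], r3$voltages[, 1])
})

test_that("halving dt changes sampled voltages at second order", {
  p <- neuron_params()
  net <- network_spec(matrix(0, 1, 1))
  set.seed(4)
  tt <- sort(runif(50, 0, 900))
  trains <- list(times = list(tt), strengths = list(rep(0.02, 50)))
  v <- lapply(c(0.2, 0.1, 0.05), function(dt)
    simulate_network(net, p, trains, duration = 1000, dt = dt, fs = 1,
                     seed = 1, v0 = 0.3)$voltages[, 1])
  e1 <- max(abs(v[[1]] - v[[3]]))
  e2 <- max(abs(v[[2]] - v[[3]]))
  # second-order scheme: quartering the error when halving dt (allow slack)
  expect_lt(e2, e1 / 3)
})

test_that("EIF with the spike current disabled reproduces IF trajectories", {
  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  d <- drive_spec(rate = 0.5, strength = 0.02)
  p_if <- neuron_params()
  p_eif0 <- neuron_params(delta_T = 0)
  net_if <- network_spec(A, S_ee = 0.02, model_kind = "IF")
  net_eif <- network_spec(A, S_ee = 0.02, model_kind = "EIF")
  r1 <- simulate_network(net_if, p_if, d, duration = 5e3, seed = 3)
  r2 <- simulate_network(net_eif, p_eif0, d, duration = 5e3, seed = 3)
  expect_lt(max(abs(r1$voltages - r2$voltages)), 1e-6)
  expect_equal(r1$spikes, r2$spikes)
})

test_that("the EIF model spikes via the divergence cutoff and stays finite", {
  net <- network_spec(matrix(0, 1, 1), model_kind = "EIF")
  rec <- simulate_network(net, drive = drive_spec(rate = 0.7, strength = 0.02),
                          duration = 10e3, seed = 9)
  expect_gt(length(rec$spikes[[1]]), 10)
  expect_true(all(is.finite(rec$voltages)))
  expect_true(all(rec$voltages <= neuron_params()$V_cut + 1e-9))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(neuron_params(tau_E = -1), "positive")
  expect_error(neuron_params(V_cut = 0.5), "V_cut")
  expect_error(drive_spec(rate = -1), "rates")
  expect_error(simulate_network(two_neuron_net(), duration = 0.1), "duration")
  expect_error(simulate_network(two_neuron_net(), dt = 1), "dt")
})
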