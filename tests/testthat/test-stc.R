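test_that("STC of a signal with planted spike-locked structure finds it", {
  set.seed(1)
  fs <- 1
  n <- 20000
  sig <- rnorm(n)
  spikes <- sort(sample(500:19500, 300))
  # plant a deflection 3 samples after each "spike"
  sig[spikes + 3] <- sig[spikes + 3] + 1
  sig <- sig - mean(sig)
  curve <- spike_triggered_correlation(sig, spikes, lag_window = 10, fs = fs)
  expect_equal(curve$lags, -10:10)
  k <- which(curve$lags == 3)
  expect_gt(curve$values[k], 0.8)
  expect_lt(max(abs(curve$values[-k])), 3 / sqrt(curve$n_triggers) + 0.2)
})

test_that("flat white-noise signal stays inside the shuffle-null band", {
  set.seed(2)
  n <- 20000
  sig <- rnorm(n); sig <- sig - mean(sig)
  spikes <- sort(runif(200, 100, n - 100))
  curve <- spike_triggered_correlation(sig, spikes, lag_window = 20, fs = 1)
  env <- stc_null_envelope(sig, spikes, duration = n, lag_window = 20, fs = 1,
                           n_shuffle = 300, level = 0.999, seed = 3)
  inside <- curve$values >= env$lower & curve$values <= env$upper
  expect_gt(mean(inside), 0.95)
})

test_that("voltage STC shows spurious reverse structure that whitening removes", {
  # the central contrast: with a 1 -> 2 synapse only, the voltage STC in the
  # unconnected direction (signal 1 triggered on spikes of 2) deviates from
  # zero at positive lags, while the residual STC does not
  rec <- sim_two_neuron(rate = 0.25, duration = 120e3, seed = 6)
  s <- demean(rec)
  dur <- rec$duration

  exceed <- function(curve, env) {
    pos <- curve$lags > 0
    (curve$values > env$upper | curve$values < env$lower)[pos]
  }
  # unconnected direction on voltages: significant positive-lag deviation
  v1 <- s$data[, 1]
  cv <- spike_triggered_correlation(v1, rec$spikes[[2]], 50, fs = 1)
  ev <- stc_null_envelope(v1, rec$spikes[[2]], dur, 50, fs = 1,
                          n_shuffle = 500, seed = 1)
  expect_gt(sum(exceed(cv, ev)), 2)

  # connected direction on voltages: also significant (true synapse)
  v2 <- s$data[, 2]
  cv2 <- spike_triggered_correlation(v2, rec$spikes[[1]], 50, fs = 1)
  ev2 <- stc_null_envelope(v2, rec$spikes[[1]], dur, 50, fs = 1,
                           n_shuffle = 500, seed = 2)
  expect_gt(sum(exceed(cv2, ev2)), 2)

  # residuals: unconnected direction statistically vanishes at positive lags,
  # connected direction survives whitening
  fit <- fit_var_yule_walker(s, select_order_bic(s, 20)$order)
  r1 <- fit$residuals[, 1] - mean(fit$residuals[, 1])
  cr <- residual_stc(fit, rec$spikes[[2]], channel = 1, lag_window = 50)
  er <- stc_null_envelope(r1, rec$spikes[[2]], dur, 50, fs = 1,
                          offset = fit$order, n_shuffle = 500, seed = 3)
  # family-wise: the residual curve stays in the null band at all lags beyond
  # the one-sample instantaneous-causality window of the sampling grid
  expect_lt(max(abs(cr$values[cr$lags > 1 / rec$fs])), er$max_abs)

  r2 <- fit$residuals[, 2] - mean(fit$residuals[, 2])
  cr2 <- residual_stc(fit, rec$spikes[[1]], channel = 2, lag_window = 50)
  er2 <- stc_null_envelope(r2, rec$spikes[[1]], dur, 50, fs = 1,
                           offset = fit$order, n_shuffle = 500, seed = 4)
  expect_gt(sum(exceed(cr2, er2)), 0)
})

test_that("coefficient approximations track planted lagged correlation", {
  set.seed(8)
  n <- 50000
  eta <- rnorm(n)
  eps <- rnorm(n)
  eps[4:n] <- eps[4:n] + 0.3 * eta[1:(n - 3)]  # lag-3 correlation only
  eps <- eps - mean(eps); eta <- eta - mean(eta)
  ap <- approx_regression_coefficients(eps, eta, order = 5)
  expect_equal(unname(ap$b[3, "approx"]), 0.3, tolerance = 0.05)
  expect_lt(max(abs(ap$b[-3, "approx"])), 0.03)
  # approximation agrees with the exactly solved joint-regression coefficients
  expect_lt(max(abs(ap$b[, "approx"] - ap$b[, "exact"])), 0.03)
  expect_lt(max(abs(ap$d[, "approx"])), 0.03)
})

test_that("uncorrelated residual streams give near-zero approximations", {
  set.seed(9)
  eps <- rnorm(2e4); eta <- rnorm(2e4)
  ap <- approx_regression_coefficients(eps - mean(eps), eta - mean(eta), 4)
  expect_lt(max(abs(ap$b[, "approx"])), 0.03)
  expect_lt(max(abs(ap$d[, "approx"])), 0.03)
  g <- gc_from_residual_crosscorr(eps, eta, 4)
  expect_lt(max(g), 4 * 4 / 2e4)
})

test_that("GC from residual cross-correlations matches a constructed case", {
  set.seed(10)
  n <- 1e5
  eta <- rnorm(n)
  b <- 0.2
  eps <- rnorm(n)
  eps[2:n] <- eps[2:n] + b * eta[1:(n - 1)]
  g <- gc_from_residual_crosscorr(eps - mean(eps), eta - mean(eta), 3)
  # analytic: sum of squared cross-correlations = b^2 var(eta) / var(eps)
  expect_equal(unname(g["y_to_x"]), b^2 / (1 + b^2), tolerance = 0.02)
  expect_lt(g["x_to_y"], 4 * 3 / n)
})

test_that("GC approximation is consistent with direct GC on the neuron pair", {
  rec <- sim_two_neuron(rate = 0.5, duration = 120e3, seed = 12)
  s <- demean(rec)
  p <- select_order_bic(s, 20)$order
  ar1 <- fit_var_yule_walker(s$data[, 1, drop = FALSE], p)
  ar2 <- fit_var_yule_walker(s$data[, 2, drop = FALSE], p)
  g_apx <- gc_from_residual_crosscorr(ar1$residuals[, 1], ar2$residuals[, 1], p)
  g_dir <- pairwise_gc(s$data[, 1], s$data[, 2], p)
  expect_equal(unname(g_apx["x_to_y"]), unname(g_dir["x_to_y"]),
               tolerance = 0.3)
  # after removing the O(p/T) estimation floor, the connected direction
  # dominates the unconnected one in both estimators
  Tn <- nrow(s$data)
  expect_gt(g_apx["x_to_y"] - p / Tn, 3 * max(g_apx["y_to_x"] - p / Tn, 1e-9))
  expect_gt(g_dir["x_to_y"] - p / Tn, 3 * max(g_dir["y_to_x"] - p / Tn, 1e-9))
})

test_that("firing-reset dynamics concentrate residual energy at spike samples", {
  rec <- sim_two_neuron(rate = 0.5, duration = 60e3, seed = 14)
  s <- demean(rec)
  fit <- fit_var_yule_walker(s, 10)
  chk <- delta_residual_check(fit, rec$spikes[[1]], channel = 1)
  expect_gt(chk$concentration, 5)  # energy fraction >> time fraction

  # pure white noise with random "spikes": energy ~ time fraction
  set.seed(15)
  wn <- matrix(rnorm(2e4 * 2), ncol = 2)
  fitw <- fit_var_yule_walker(scale(wn, scale = FALSE), 5)
  fake <- sort(runif(300, 0, 2e4))
  chkw <- delta_residual_check(fitw, fake, channel = 1)
  expect_lt(abs(chkw$concentration - 1), 0.35)
})

test_that("postsynaptic spike-locked residual deflections grow with coupling", {
  conc <- vapply(c(0.01, 0.04), function(S) {
    rec <- sim_two_neuron(rate = 0.5, S = S, duration = 60e3, seed = 16)
    s <- demean(rec)
    fit <- fit_var_yule_walker(s, 10)
    # energy of neuron-2 residual at presynaptic (neuron-1) spike samples
    delta_residual_check(fit, rec$spikes[[1]], channel = 2)$concentration
  }, 1)
  expect_gt(conc[2], conc[1])
})

test_that("power-law fit recovers exact exponents and validates inputs", {
  S <- c(0.01, 0.02, 0.04, 0.08)
  expect_equal(fit_gc_coupling_law(S, 5 * S^2)$exponent, 2, tolerance = 1e-10)
  expect_equal(fit_gc_coupling_law(S, 2 * S^3)$exponent, 3, tolerance = 1e-10)
  expect_error(fit_gc_coupling_law(rev(S), 5 * S^2), "increasing")
  expect_warning(fit_gc_coupling_law(S, c(-1, 1e-4, 4e-4, 1.6e-3)),
                 "nonpositive")
  expect_error(suppressWarnings(fit_gc_coupling_law(S, c(-1, -1, 4e-4, 1.6e-3))),
               "3 usable")
})
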