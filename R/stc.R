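#' Spike-triggered correlation of a zero-mean signal
#'
#' `STC(t) = < s_j(T_{i,k} + t) >_k`: the average of the (zero-mean) signal
#' of neuron j around the spike times of a trigger neuron i, as a function of
#' the lag t.  The signal is evaluated on its sampling grid by
#' nearest-sample lookup; triggers whose lag window leaves the recording are
#' dropped.
#'
#' @param signal zero-mean numeric vector (one channel, uniformly sampled).
#' @param spikes trigger spike times (ms).
#' @param lag_window half-width of the lag window (ms); the lag grid is
#'   symmetric about zero.
#' @param fs sampling rate of `signal` (kHz).
#' @param offset index offset of `signal[1]` on the original sampling grid
#'   (used for residual channels, which drop the first p samples).
#' @return an object of class `stc_curve`: `lags` (ms), `values`,
#'   `n_triggers`.
#' @export
spike_triggered_correlation <- function(signal, spikes, lag_window = 50,
                                        fs = 1, offset = 0) {
  K <- round(lag_window * fs)
  n <- length(signal)
  idx <- round(spikes * fs) - offset
  keep <- idx - K >= 1 & idx + K <= n
  idx <- idx[keep]
  if (length(idx) == 0) stop("no retained triggers inside the recording")
  lag_idx <- -K:K
  # n_triggers x n_lags gather, then column means
  M <- outer(idx, lag_idx, `+`)
  vals <- colMeans(matrix(signal[M], nrow = length(idx)))
  structure(list(lags = lag_idx / fs, values = vals,
                 n_triggers = length(idx)),
            class = "stc_curve")
}

#' @export
print.stc_curve <- function(x, ...) {
  cat(sprintf("<stc_curve> %d lags in [%g, %g] ms, %d triggers\n",
              length(x$lags), min(x$lags), max(x$lags), x$n_triggers))
  invisible(x)
}

#' Pointwise shuffle-null envelope for an STC curve
#'
#' Circularly shifts all trigger spike times by a uniform random offset
#' (modulo the recording duration) and recomputes the STC; the pointwise
#' envelope at the requested level serves as an assumption-free null band
#' for "no spike-locked structure".
#'
#' @inheritParams spike_triggered_correlation
#' @param duration recording duration (ms), used for the circular shift.
#' @param n_shuffle number of shuffles.
#' @param level envelope level (two-sided pointwise).
#' @param seed RNG seed.
#' @return a list with `lags`, `lower`, `upper`, the shuffle `sd` per lag,
#'   and `max_abs` — the `level` quantile of the maximum absolute shuffled
#'   STC over positive lags, a family-wise band for "the whole positive-lag
#'   curve statistically vanishes".
#' @export
stc_null_envelope <- function(signal, spikes, duration, lag_window = 50,
                              fs = 1, offset = 0, n_shuffle = 1000,
                              level = 0.99, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 77L))
  K <- round(lag_window * fs)
  n <- length(signal)
  lag_idx <- -K:K
  qs <- matrix(NA_real_, n_shuffle, length(lag_idx))
  for (b in seq_len(n_shuffle)) {
    sh <- (spikes + runif(1) * duration) %% duration
    idx <- round(sh * fs) - offset
    idx <- idx[idx - K >= 1 & idx + K <= n]
    if (length(idx) == 0) next
    M <- outer(idx, lag_idx, `+`)
    qs[b, ] <- colMeans(matrix(signal[M], nrow = length(idx)))
  }
  qs <- qs[stats::complete.cases(qs), , drop = FALSE]
  pr <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pos <- lag_idx > 0
  list(lags = lag_idx / fs,
       lower = apply(qs, 2, quantile, pr[1]),
       upper = apply(qs, 2, quantile, pr[2]),
       sd = apply(qs, 2, sd),
       max_abs = quantile(apply(abs(qs[, pos, drop = FALSE]), 1, max), level))
}

#' STC of a regression residual channel
#'
#' Computes the spike-triggered correlation of the whitened residual of one
#' channel of a fitted VAR, triggered on the spike times of a (possibly
#' different) neuron.  The residual series starts p samples into the
#' recording; the alignment offset is handled internally.
#'
#' @param fit a `var_fit`.
#' @param spikes trigger spike times (ms).
#' @param channel residual channel index.
#' @inheritParams spike_triggered_correlation
#' @return an `stc_curve`.
#' @export
residual_stc <- function(fit, spikes, channel = 1, lag_window = 50, fs = 1) {
  stopifnot(inherits(fit, "var_fit"))
  r <- fit$residuals[, channel]
  spike_triggered_correlation(r - mean(r), spikes, lag_window, fs,
                              offset = fit$order)
}

#' Residual cross-covariance approximation of joint-regression coefficients
#'
#' For the bivariate case, the cross coefficients of the joint regression of
#' the whitened residual streams are approximated lag-by-lag by normalized
#' residual cross-covariances: `b_k ~ cov(eps_t, eta_{t-k}) / var(eta)` and
#' `d_k ~ cov(eta_t, eps_{t-k}) / var(eps)`, where `eps` and `eta` are the
#' autoregressive residuals of the two channels.  The exactly solved
#' joint-regression coefficients on the residual streams are returned
#' alongside for comparison.
#'
#' @param eps,eta autoregressive residual series of the two channels
#'   (equal length).
#' @param order number of lags `k = 1..order`.
#' @return a list with matrices `b` and `d` (`order x 2`, columns
#'   `approx` and `exact`).
#' @export
approx_regression_coefficients <- function(eps, eta, order) {
  stopifnot(length(eps) == length(eta))
  Tn <- length(eps)
  ve <- mean(eps^2); vh <- mean(eta^2)
  if (ve == 0 || vh == 0) stop("zero residual variance")
  ccov <- function(a, b, k)  # cov(a_t, b_{t-k}) with divisor T
    sum(a[(k + 1):Tn] * b[1:(Tn - k)]) / Tn
  b_apx <- vapply(seq_len(order), function(k) ccov(eps, eta, k) / vh, 1)
  d_apx <- vapply(seq_len(order), function(k) ccov(eta, eps, k) / ve, 1)
  jr <- fit_var_yule_walker(cbind(eps, eta), order)
  b_ex <- jr$coefficients[1, 2, ]   # eta lags in the eps equation
  d_ex <- jr$coefficients[2, 1, ]   # eps lags in the eta equation
  list(b = cbind(approx = b_apx, exact = b_ex),
       d = cbind(approx = d_apx, exact = d_ex))
}

#' GC approximated from residual cross-correlations
#'
#' Approximates the bivariate GC as the sum over lags `1..order` of the
#' squared residual cross-correlation,
#' `F_{y->x} ~ sum_k cov(eps_t, eta_{t-k})^2 / (var(eps) var(eta))`,
#' the small-correlation limit of the exact Yule-Walker solution on the
#' residual streams.
#'
#' @inheritParams approx_regression_coefficients
#' @return named vector `c(y_to_x, x_to_y)` of approximate GC values.
#' @export
gc_from_residual_crosscorr <- function(eps, eta, order) {
  stopifnot(length(eps) == length(eta))
  Tn <- length(eps)
  ve <- mean(eps^2); vh <- mean(eta^2)
  if (ve == 0 || vh == 0) stop("zero residual variance")
  cc <- vapply(seq_len(order), function(k)
    sum(eps[(k + 1):Tn] * eta[1:(Tn - k)]) / Tn, 1)     # cov(eps_t, eta_{t-k})
  cc_rev <- vapply(seq_len(order), function(k)
    sum(eta[(k + 1):Tn] * eps[1:(Tn - k)]) / Tn, 1)     # cov(eta_t, eps_{t-k})
  c(y_to_x = sum(cc^2) / (ve * vh), x_to_y = sum(cc_rev^2) / (ve * vh))
}

#' Spike-locked residual energy report
#'
#' The firing-reset dynamics concentrate the regression residual in the
#' samples at and just after each spike of the same neuron, which is what
#' makes the residual effectively delta-like.  This diagnostic reports the
#' fraction of residual energy carried by spike-associated samples (the
#' sample containing the spike and its successor, covering the reset
#' transient) against the fraction of time those samples occupy.
#'
#' @param fit a `var_fit`.
#' @param spikes spike times (ms) of the neuron whose residual is examined.
#' @param channel residual channel index.
#' @param fs sampling rate (kHz).
#' @return a list with `energy_fraction`, `time_fraction` and their ratio
#'   `concentration`; degenerate (no usable spikes) gives `NA`s.
#' @export
delta_residual_check <- function(fit, spikes, channel = 1, fs = 1) {
  stopifnot(inherits(fit, "var_fit"))
  r <- fit$residuals[, channel]
  n <- length(r)
  idx <- round(spikes * fs) - fit$order
  idx <- unique(sort(c(idx, idx + 1L)))
  idx <- idx[idx >= 1 & idx <= n]
  if (length(idx) == 0)
    return(list(energy_fraction = NA_real_, time_fraction = NA_real_,
                concentration = NA_real_))
  ef <- sum(r[idx]^2) / sum(r^2)
  tf <- length(idx) / n
  list(energy_fraction = ef, time_fraction = tf, concentration = ef / tf)
}

#' Fit the GC-versus-coupling-strength power law
#'
#' Least-squares slope of `log(F)` against `log(S)` over a sweep of coupling
#' strengths; the theory for pulse-coupled conductance-based neurons at
#' small coupling predicts a slope of 2 (GC quadratic in S).
#'
#' @param strengths strictly positive, increasing coupling strengths.
#' @param gc_values estimated GC in the connected direction at each
#'   strength; nonpositive values are excluded with a warning.
#' @return an object of class `coupling_scan`: `exponent` (log-log slope),
#'   `coefficient` (prefactor), and the points used.
#' @export
fit_gc_coupling_law <- function(strengths, gc_values) {
  stopifnot(length(strengths) == length(gc_values))
  if (any(diff(strengths) <= 0) || any(strengths <= 0))
    stop("strengths must be strictly positive and increasing")
  ok <- gc_values > 0
  if (!all(ok)) warning("excluding ", sum(!ok), " nonpositive GC value(s)")
  if (sum(ok) < 3) stop("fewer than 3 usable points for the log-log fit")
  f <- lm(log(gc_values[ok]) ~ log(strengths[ok]))
  structure(list(exponent = unname(coef(f)[2]),
                 coefficient = exp(unname(coef(f)[1])),
                 strengths = strengths[ok], gc_values = gc_values[ok]),
            class = "coupling_scan")
}

#' @export
print.coupling_scan <- function(x, ...) {
  cat(sprintf("<coupling_scan> %d points, log-log slope %.3f, prefactor %.3g\n",
              length(x$strengths), x$exponent, x$coefficient))
  invisible(x)
}
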