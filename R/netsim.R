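#' Neuron model parameters
#'
#' Membrane and synaptic parameters of the conductance-based
#' integrate-and-fire (IF) neuron and its exponential variant (EIF), in
#' normalized units: the leak reversal is 0 and the firing threshold is 1, so
#' only time (ms) keeps a physical dimension and conductances are expressed
#' in ms^-1.  Defaults follow the standard normalized-unit convention of the
#' conductance-based modeling literature and can be overridden freely.
#'
#' @param g_L leak conductance (ms^-1).
#' @param E_L leak reversal potential (normalized units).
#' @param E_E,E_I excitatory / inhibitory reversal potentials.
#' @param V_th firing threshold (IF model).
#' @param V_reset reset voltage after a spike.
#' @param tau_E,tau_I excitatory / inhibitory conductance decay times (ms).
#' @param tau_ref absolute refractory period (ms).
#' @param delta_T EIF slope factor; values below 1e-8 disable the spike
#'   current, reducing the EIF model exactly to the IF model.
#' @param V_T EIF spike-initiation threshold.
#' @param V_cut EIF numerical divergence cutoff; crossing it is identified as
#'   spike emission.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(g_L = 0.05, E_L = 0, E_E = 14 / 3, E_I = -2 / 3,
                          V_th = 1, V_reset = 0, tau_E = 2, tau_I = 5,
                          tau_ref = 2, delta_T = 0.35, V_T = 1, V_cut = 5) {
  p <- list(g_L = g_L, E_L = E_L, E_E = E_E, E_I = E_I, V_th = V_th,
            V_reset = V_reset, tau_E = tau_E, tau_I = tau_I,
            tau_ref = tau_ref, delta_T = delta_T, V_T = V_T, V_cut = V_cut)
  stopifnot(is.numeric(unlist(p)), length(unlist(p)) == 12L)
  if (!(E_I < E_L && E_L < V_th && V_th < E_E))
    stop("reversal potentials must satisfy E_I < E_L < V_th < E_E")
  if (tau_E <= 0 || tau_I <= 0 || tau_ref <= 0)
    stop("tau_E, tau_I and tau_ref must be positive")
  if (delta_T < 0) stop("delta_T must be >= 0")
  if (V_cut <= V_th) stop("V_cut must exceed V_th")
  structure(p, class = "neuron_params")
}

#' Feedforward Poisson drive specification
#'
#' Each neuron receives an independent homogeneous Poisson train of
#' conductance kicks, plus optionally one shared ("common") Poisson train
#' delivered identically to all (or a subset of) neurons.
#'
#' @param rate independent Poisson rate per neuron (events/ms).
#' @param strength excitatory conductance jump per independent event.
#' @param common_rate rate of the shared Poisson train (events/ms).
#' @param common_strength conductance jump per shared event.
#' @param common_targets neuron indices receiving the shared train
#'   (default: all).
#' @return an object of class `drive_spec`.
#' @export
drive_spec <- function(rate = 0.7, strength = 0.02, common_rate = 0,
                       common_strength = strength, common_targets = NULL) {
  if (rate < 0 || common_rate < 0) stop("Poisson rates must be >= 0")
  if (strength < 0 || common_strength < 0) stop("input strengths must be >= 0")
  structure(list(rate = rate, strength = strength, common_rate = common_rate,
                 common_strength = common_strength,
                 common_targets = common_targets),
            class = "drive_spec")
}

#' Fraction of the total Poisson input that is shared
#'
#' Returns `common_rate / (rate + common_rate)`, the rate fraction of the
#' common train among all feedforward events a neuron receives.
#'
#' @param drive a [drive_spec()].
#' @return a number in \[0, 1\].
#' @export
common_input_fraction <- function(drive) {
  stopifnot(inherits(drive, "drive_spec"))
  tot <- drive$rate + drive$common_rate
  if (tot <= 0) stop("common input fraction undefined when both rates are zero")
  drive$common_rate / tot
}

#' Network specification
#'
#' Bundles the directed 0/1 adjacency matrix (entry `adjacency[j, i] = 1`
#' means neuron j is presynaptic to neuron i), the neuron types, the four
#' class coupling strengths and the model kind.  Excitatory neurons occupy
#' indices `1..n_exc`, inhibitory neurons the remainder.
#'
#' @param adjacency square 0/1 matrix with zero diagonal (no autapses).
#' @param n_exc,n_inh number of excitatory / inhibitory neurons; together
#'   they must equal `nrow(adjacency)`.
#' @param S_ee,S_ie,S_ei,S_ii coupling strengths (conductance jumps) by
#'   connection class, named target-source: `S_ie` is excitatory-to-
#'   inhibitory.  All must be nonnegative; the sign of the synaptic effect is
#'   carried by the reversal potentials.
#' @param model_kind `"IF"` or `"EIF"`.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(adjacency, n_exc = nrow(adjacency), n_inh = 0,
                         S_ee = 0.02, S_ie = S_ee, S_ei = 0.02, S_ii = S_ei,
                         model_kind = c("IF", "EIF")) {
  model_kind <- match.arg(model_kind)
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (n_exc < 0 || n_inh < 0 || n_exc + n_inh != n)
    stop("n_exc + n_inh must equal nrow(adjacency)")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0)) stop("autapses are not allowed (zero diagonal)")
  if (min(S_ee, S_ie, S_ei, S_ii) < 0) stop("coupling strengths must be >= 0")
  structure(list(adjacency = adjacency, n_exc = as.integer(n_exc),
                 n_inh = as.integer(n_inh),
                 S = c(S_ee = S_ee, S_ie = S_ie, S_ei = S_ei, S_ii = S_ii),
                 model_kind = model_kind),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d neurons (%d exc, %d inh), %s model, %d edges\n",
              nrow(x$adjacency), x$n_exc, x$n_inh, x$model_kind,
              sum(x$adjacency)))
  invisible(x)
}

#' Random directed network
#'
#' Each off-diagonal adjacency entry is set to 1 independently with
#' probability `density` (Erdos-Renyi directed graph, no autapses).
#'
#' @param n_exc,n_inh numbers of excitatory / inhibitory neurons.
#' @param density connection probability in \[0, 1\].
#' @param seed integer seed; the draw is reproducible.
#' @param ... passed to [network_spec()] (coupling strengths, model kind).
#' @return a `network_spec`.
#' @export
generate_random_network <- function(n_exc, n_inh = 0, density = 0.05,
                                    seed = 1, ...) {
  if (n_exc < 0 || n_inh < 0 || n_exc + n_inh < 2)
    stop("need at least two neurons")
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  n <- n_exc + n_inh
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0L))
  A <- matrix(rbinom(n * n, 1L, density), n, n)
  diag(A) <- 0L
  network_spec(A, n_exc = n_exc, n_inh = n_inh, ...)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample feedforward Poisson spike trains
#'
#' Draws one independent homogeneous Poisson train per neuron and, if
#' `common_rate > 0`, one shared train copied identically into every targeted
#' neuron's event list.  Per-neuron substreams are derived from the master
#' seed, so adding neurons leaves existing trains unchanged.
#'
#' @param drive a [drive_spec()].
#' @param n_neurons number of neurons.
#' @param duration total time (ms).
#' @param seed master integer seed.
#' @return a list with `times` and `strengths` (lists of numeric vectors,
#'   one per neuron, times ascending) plus the shared train in `common`.
#' @export
sample_poisson_trains <- function(drive, n_neurons, duration, seed = 1) {
  stopifnot(inherits(drive, "drive_spec"))
  if (duration <= 0) stop("duration must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  draw <- function(rate, s) {
    if (rate <= 0) return(numeric(0))
    set.seed(s)
    n <- ceiling(rate * duration + 6 * sqrt(rate * duration) + 20)
    t <- cumsum(rexp(n, rate))
    while (t[length(t)] < duration) t <- c(t, t[length(t)] + cumsum(rexp(n, rate)))
    t[t < duration]
  }
  common <- draw(drive$common_rate, derive_seed(seed, 1000003L))
  targets <- drive$common_targets %||% seq_len(n_neurons)
  times <- strengths <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    ti <- draw(drive$rate, derive_seed(seed, i))
    si <- rep(drive$strength, length(ti))
    if (length(common) && i %in% targets) {
      ti <- c(ti, common)
      si <- c(si, rep(drive$common_strength, length(common)))
      o <- order(ti)
      ti <- ti[o]; si <- si[o]
    }
    times[[i]] <- ti
    strengths[[i]] <- si
  }
  list(times = times, strengths = strengths, common = common)
}

# Per-edge conductance-jump matrix from class coupling strengths.
coupling_matrix <- function(network) {
  n <- nrow(network$adjacency)
  type_e <- seq_len(n) <= network$n_exc
  W <- matrix(0, n, n)
  S <- network$S
  for (j in seq_len(n)) for (i in seq_len(n)) {
    if (network$adjacency[j, i] == 1) {
      W[j, i] <- if (type_e[j]) {
        if (type_e[i]) S[["S_ee"]] else S[["S_ie"]]
      } else {
        if (type_e[i]) S[["S_ei"]] else S[["S_ii"]]
      }
    }
  }
  W
}

#' Simulate a pulse-coupled conductance-based network
#'
#' Evolves the network under independent (and optionally common) Poisson
#' drive with a fixed-step second-order Runge-Kutta scheme: conductances
#' decay exactly between events, feedforward events split the integration
#' step at their exact times, threshold crossings are located by linear
#' interpolation, and the voltage is clamped at reset for the absolute
#' refractory period.  The recorded voltage of each neuron is its average
#' over consecutive sampling windows of width `1/fs` ms.
#'
#' @param network a [network_spec()].
#' @param params a [neuron_params()].
#' @param drive a [drive_spec()], or a precomputed event list as returned by
#'   [sample_poisson_trains()].
#' @param duration simulated time (ms).
#' @param dt integration step (ms); must satisfy `dt <= tau_E / 10` and
#'   `1/(fs*dt)` must be an integer.
#' @param fs sampling rate (kHz).
#' @param seed master seed (drive realization and initial voltages).
#' @param v0 optional initial voltages; default uniform in
#'   \[V_reset, V_th\).
#' @return a `simulation_record`: list with `voltages`
#'   (`n_samples x n` matrix), `times` (sample times, ms), `spikes`
#'   (per-neuron spike-time vectors), `fs`, `dt`, `duration`, and full
#'   `provenance`.
#' @export
simulate_network <- function(network, params = neuron_params(),
                             drive = drive_spec(), duration = 600e3,
                             dt = 0.05, fs = 1, seed = 1, v0 = NULL) {
  stopifnot(inherits(network, "network_spec"), inherits(params, "neuron_params"))
  n <- nrow(network$adjacency)
  if (duration < 1 / fs) stop("duration shorter than one sampling window")
  if (dt > params$tau_E / 10) stop("dt must resolve conductance decay (dt <= tau_E/10)")
  if (fs * dt > 1 + 1e-12) stop("each sampling window must contain >= 1 integration step")

  if (inherits(drive, "drive_spec")) {
    trains <- sample_poisson_trains(drive, n, duration, seed = seed)
    drive_prov <- drive
  } else {
    trains <- drive
    drive_prov <- attr(drive, "spec")
  }
  if (is.null(v0)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 999999L))
    v0 <- runif(n, params$V_reset, params$V_th)
    .Random.seed_restore(old)
  }

  W <- coupling_matrix(network)
  is_exc <- seq_len(n) <= network$n_exc
  par <- c(unclass(params),
           list(kind = if (network$model_kind == "EIF") 1L else 0L))
  out <- .sim_network_cpp(W, is_exc, trains$times, trains$strengths, par,
                          duration, dt, fs, as.numeric(v0))
  if (!all(is.finite(out$voltages))) stop("non-finite recorded voltages")
  n_samples <- nrow(out$voltages)
  structure(list(voltages = out$voltages,
                 times = seq_len(n_samples) / fs,
                 spikes = out$spikes,
                 fs = fs, dt = dt, duration = duration,
                 provenance = list(network = network, params = params,
                                   drive = drive_prov, seed = seed)),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  n <- ncol(x$voltages)
  rates <- vapply(x$spikes, length, 1L) / x$duration * 1000
  cat(sprintf("<simulation_record> %d neurons, %.3g s at fs = %g kHz (dt = %g ms)\n",
              n, x$duration / 1000, x$fs, x$dt))
  cat(sprintf("  firing rates (Hz): min %.2f, median %.2f, max %.2f\n",
              min(rates), stats::median(rates), max(rates)))
  invisible(x)
}

#' Per-neuron firing rates of a simulation
#'
#' @param record a `simulation_record`.
#' @return firing rates in Hz.
#' @export
firing_rates <- function(record) {
  vapply(record$spikes, length, 1L) / record$duration * 1000
}
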