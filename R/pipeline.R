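#' Threshold a GC matrix into a causal adjacency
#'
#' Off-diagonal entries strictly exceeding the threshold become 1; the
#' diagonal is forced to zero.
#'
#' @param gc a `gc_matrix`.
#' @param threshold nonnegative threshold on the GC scale.
#' @param method label recorded in the result.
#' @return an object of class `causal_adjacency`: 0/1 `matrix`,
#'   `threshold_used`, `method`.
#' @export
threshold_gc <- function(gc, threshold, method = "manual") {
  if (threshold < 0) stop("threshold must be >= 0")
  A <- 1L * (gc$values > threshold)
  diag(A) <- 0L
  structure(list(matrix = A, threshold_used = threshold, method = method),
            class = "causal_adjacency")
}

#' Gap threshold from ranked GC values
#'
#' Sorts the off-diagonal GC values on a log scale and places the threshold
#' at the geometric midpoint of the largest consecutive gap.  The gap
#' magnitude (in decades) is returned so callers can detect the absence of a
#' clear gap (typical for mixed excitatory/inhibitory networks).
#'
#' @param gc a `gc_matrix`.
#' @param min_gap gaps below this many decades are flagged as weak (half a
#'   decade by default, appropriate for networks of tens of neurons).
#' @return a list with `threshold`, `gap_decades`, `clear_gap`, and the
#'   ranked values.
#' @export
gap_threshold <- function(gc, min_gap = 0.5) {
  v <- gc$values[row(gc$values) != col(gc$values)]
  if (length(v) < 2) stop("need at least two off-diagonal GC values")
  v <- pmax(v, 1e-300)
  lv <- sort(log10(v))
  if (max(lv) - min(lv) < 1e-12) {
    warning("all GC values equal: no gap")
    return(list(threshold = 10^lv[1], gap_decades = 0, clear_gap = FALSE,
                ranked = sort(v, decreasing = TRUE)))
  }
  d <- diff(lv)
  k <- which.max(d)
  list(threshold = 10^((lv[k] + lv[k + 1]) / 2),
       gap_decades = d[k],
       clear_gap = d[k] >= min_gap,
       ranked = sort(v, decreasing = TRUE))
}

#' Compare causal and structural adjacency
#'
#' Off-diagonal elementwise agreement between the thresholded causal
#' adjacency and the structural (synaptic) adjacency.
#'
#' @param structural 0/1 matrix or `network_spec`.
#' @param causal `causal_adjacency` or 0/1 matrix.
#' @return an object of class `reconstruction_report`: `accuracy`,
#'   `false_positives`, `false_negatives`, `n_pairs`.
#' @export
compare_adjacency <- function(structural, causal) {
  A <- if (inherits(structural, "network_spec")) structural$adjacency
       else as.matrix(structural)
  C <- if (inherits(causal, "causal_adjacency")) causal$matrix
       else as.matrix(causal)
  if (!all(dim(A) == dim(C))) stop("adjacency shape mismatch")
  off <- row(A) != col(A)
  fp <- sum(C[off] == 1 & A[off] == 0)
  fn <- sum(C[off] == 0 & A[off] == 1)
  n_pairs <- sum(off)
  structure(list(accuracy = sum(A[off] == C[off]) / n_pairs,
                 false_positives = fp, false_negatives = fn,
                 n_pairs = n_pairs),
            class = "reconstruction_report")
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat(sprintf("<reconstruction_report> accuracy %.4f (%d FP, %d FN of %d pairs)\n",
              x$accuracy, x$false_positives, x$false_negatives, x$n_pairs))
  invisible(x)
}

#' Binarize spike trains onto a sampling grid
#'
#' Encodes each neuron's spike train as a binary vector: 1 in a bin that
#' contains a spike, 0 otherwise.  The bin width `1/fs_bin` must not exceed
#' the refractory period, so a bin can contain at most one spike; two spikes
#' in one bin raise an error.
#'
#' @param spikes list of per-neuron spike-time vectors (ms), or a
#'   `simulation_record`.
#' @param fs_bin binning rate (kHz).
#' @param duration recording length (ms); taken from the record if given.
#' @return a `ts_set` of 0/1 channels (demean before GC).
#' @export
binarize_spike_trains <- function(spikes, fs_bin = 1, duration = NULL) {
  if (inherits(spikes, "simulation_record")) {
    duration <- duration %||% spikes$duration
    spikes <- spikes$spikes
  }
  if (is.null(duration)) stop("duration required")
  n_bins <- floor(duration * fs_bin)
  X <- matrix(0, n_bins, length(spikes))
  for (i in seq_along(spikes)) {
    idx <- floor(spikes[[i]] * fs_bin) + 1L
    idx <- idx[idx >= 1 & idx <= n_bins]
    if (anyDuplicated(idx))
      stop("two spikes in one bin: decrease the bin width below tau_ref")
    X[idx, i] <- 1
  }
  ts_set(X, fs = fs_bin)
}

#' Average voltages over a partition of neurons
#'
#' Collapses groups of neurons into effective channels by the unweighted
#' mean of their member voltages (an LFP-like population signal including
#' spike-reset transients).  Singleton blocks pass through unchanged.
#'
#' @param record a `simulation_record` or `ts_set`.
#' @param partition list of disjoint index vectors, each nonempty.
#' @return a `ts_set` with one channel per block.
#' @export
average_subnetwork_voltage <- function(record, partition) {
  s <- as_ts_set(record)
  idx <- unlist(partition)
  if (anyDuplicated(idx)) stop("partition blocks must be disjoint")
  if (any(vapply(partition, length, 1L) == 0)) stop("empty partition block")
  if (any(idx < 1 | idx > ncol(s$data))) stop("partition index out of range")
  Y <- vapply(partition, function(b)
    rowMeans(s$data[, b, drop = FALSE]), numeric(nrow(s$data)))
  ts_set(Y, fs = s$fs,
         labels = vapply(partition, function(b) paste(b, collapse = "+"), ""))
}

#' End-to-end network reconstruction
#'
#' Runs the full workflow on a recording: demean (voltage mode) or binarize
#' then demean (spike-train mode), conditional GC with BIC order selection,
#' thresholding (chi-squared p-value test or ranked-GC gap), and, if the
#' structural adjacency is known, accuracy scoring.
#'
#' @param record a `simulation_record`, or a `ts_set` in voltage mode.
#' @param mode `"voltage"` or `"spikes"`.
#' @param threshold `"pvalue"` or `"gap"`, or a numeric threshold.
#' @param alpha significance level of the chi-squared test.
#' @param bonferroni Bonferroni-correct across directed pairs.
#' @param order,max_order regression order (fixed or BIC-selected).
#' @param structural optional structural adjacency for scoring (taken from
#'   the record's provenance when available).
#' @param fs_bin binning rate for spike-train mode (kHz).
#' @return a list with `gc`, `threshold`, `causal`, and (when the structure
#'   is known) `report`.
#' @export
reconstruct <- function(record, mode = c("voltage", "spikes"),
                        threshold = c("pvalue", "gap"), alpha = 0.01,
                        bonferroni = FALSE, order = NULL, max_order = 30,
                        structural = NULL, fs_bin = 1) {
  mode <- match.arg(mode)
  s <- if (mode == "spikes") binarize_spike_trains(record, fs_bin = fs_bin)
       else as_ts_set(record)
  s <- demean(s)
  gc <- conditional_gc_matrix(s, order = order, max_order = max_order,
                              mode = if (mode == "spikes") "spike_train" else "voltage")
  if (is.numeric(threshold)) {
    th <- threshold
    method <- "manual"
  } else {
    method <- match.arg(threshold)
    th <- if (method == "gap") gap_threshold(gc)$threshold
          else gc_significance_threshold(gc, alpha, bonferroni)
  }
  causal <- threshold_gc(gc, th, method = method)
  out <- list(gc = gc, threshold = th, causal = causal)
  if (is.null(structural) && inherits(record, "simulation_record"))
    structural <- record$provenance$network
  if (!is.null(structural))
    out$report <- compare_adjacency(structural, causal)
  out
}

#' Minimal data length for successful reconstruction
#'
#' For each candidate recording length, the full pipeline (simulate, GC,
#' threshold, compare) is run over several seeds; a length "succeeds" when
#' the majority of seeds reconstruct the structural adjacency exactly.  One
#' long simulation per seed is truncated to each length.
#'
#' @param network,params,drive simulation inputs.
#' @param lengths increasing recording lengths (ms).
#' @param mode `"voltage"` or `"spikes"`.
#' @param n_seeds seeds per length (majority rule).
#' @param alpha significance level.
#' @param max_order BIC search range.
#' @param fs sampling rate (kHz).
#' @param seed master seed.
#' @return a list with the per-length success `table` (data.frame) and
#'   `minimal_length` (NA if none succeeded).
#' @export
minimal_data_length_sweep <- function(network, params = neuron_params(),
                                      drive = drive_spec(), lengths,
                                      mode = "voltage", n_seeds = 5,
                                      alpha = 0.01, max_order = 20, fs = 1,
                                      seed = 1) {
  if (any(diff(lengths) <= 0)) stop("lengths must be increasing")
  n <- nrow(network$adjacency)
  succ <- matrix(FALSE, length(lengths), n_seeds)
  for (s in seq_len(n_seeds)) {
    rec <- simulate_network(network, params, drive,
                            duration = max(lengths), fs = fs,
                            seed = derive_seed(seed, 5000L + s))
    for (li in seq_along(lengths)) {
      L <- lengths[li]
      sub <- rec
      sub$voltages <- rec$voltages[seq_len(floor(L * fs)), , drop = FALSE]
      sub$spikes <- lapply(rec$spikes, function(v) v[v < L])
      sub$duration <- L
      r <- reconstruct(sub, mode = mode, threshold = "pvalue", alpha = alpha,
                       max_order = max_order)
      succ[li, s] <- r$report$accuracy == 1
    }
  }
  ok <- rowMeans(succ) > 0.5
  list(table = data.frame(length_ms = lengths, success_rate = rowMeans(succ),
                          majority_success = ok),
       minimal_length = if (any(ok)) lengths[which(ok)[1]] else NA_real_)
}

#' GC degradation under common Poisson input
#'
#' For each common-input fraction, the two-neuron simulation is rerun with
#' the same total input rate split between an independent and a shared
#' Poisson train, and the GC in both directions is computed.  Reported are
#' the unconnected/connected ratio (degradation grows toward 1) and its
#' inverse (the separation, which shrinks), for the edge `1 -> 2`.
#'
#' @param network a two-neuron `network_spec` with edge 1 -> 2 only.
#' @param params neuron parameters.
#' @param total_rate total feedforward rate per neuron (events/ms).
#' @param strength feedforward strength.
#' @param fractions common-input fractions in \[0, 1).
#' @param duration recording length (ms).
#' @param n_seeds averaged seeds per fraction.
#' @param order fixed regression order (NULL: BIC).
#' @param fs sampling rate (kHz).
#' @param seed master seed.
#' @return data.frame: fraction, gc_connected, gc_unconnected,
#'   ratio_unconn_over_conn, ratio_conn_over_unconn.
#' @export
common_input_sweep <- function(network, params = neuron_params(),
                               total_rate = 0.7, strength = 0.02,
                               fractions = seq(0, 0.4, by = 0.1),
                               duration = 120e3, n_seeds = 3, order = NULL,
                               fs = 1, seed = 1) {
  if (any(fractions < 0 | fractions >= 1)) stop("fractions must be in [0, 1)")
  res <- lapply(fractions, function(phi) {
    fc <- fu <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      drv <- drive_spec(rate = (1 - phi) * total_rate, strength = strength,
                        common_rate = phi * total_rate,
                        common_strength = strength)
      rec <- simulate_network(network, params, drv, duration = duration,
                              fs = fs, seed = derive_seed(seed, 900L + s))
      gc <- conditional_gc_matrix(demean(rec), order = order)
      fc[s] <- gc$values[1, 2]
      fu[s] <- gc$values[2, 1]
    }
    c(gc_connected = mean(fc), gc_unconnected = mean(fu))
  })
  res <- do.call(rbind, res)
  data.frame(fraction = fractions,
             gc_connected = res[, 1], gc_unconnected = res[, 2],
             ratio_unconn_over_conn = res[, 2] / res[, 1],
             ratio_conn_over_unconn = res[, 1] / res[, 2])
}
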