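#' Multichannel time-series container
#'
#' A light container for uniformly sampled, zero-mean multichannel data:
#' a `T x m` numeric matrix plus the sampling rate and channel labels.
#'
#' @param data numeric matrix, one column per channel.
#' @param fs sampling rate (kHz).
#' @param labels channel labels (default column names or indices).
#' @return an object of class `ts_set`.
#' @export
ts_set <- function(data, fs = 1, labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  labels <- labels %||% colnames(data) %||% as.character(seq_len(ncol(data)))
  structure(list(data = data, fs = fs, labels = labels), class = "ts_set")
}

as_ts_set <- function(x, fs = 1) {
  if (inherits(x, "ts_set")) return(x)
  if (inherits(x, "simulation_record")) return(ts_set(x$voltages, fs = x$fs))
  ts_set(as.matrix(x), fs = fs)
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> %d samples x %d channels at %g kHz\n",
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Subtract the sample mean from every channel
#'
#' All regressions assume zero-mean series; constant channels are rejected
#' because their Granger causality is undefined.
#'
#' @param x a `ts_set`, `simulation_record`, or numeric matrix.
#' @param fs sampling rate, used only when `x` is a bare matrix.
#' @return a demeaned `ts_set`.
#' @export
demean <- function(x, fs = 1) {
  s <- as_ts_set(x, fs = fs)
  if (nrow(s$data) < 2) stop("need at least two samples")
  sds <- apply(s$data, 2, sd)
  if (any(sds == 0))
    stop("constant channel(s): ", paste(which(sds == 0), collapse = ", "),
         " (zero variance makes GC undefined)")
  s$data <- sweep(s$data, 2, colMeans(s$data))
  s
}

#' Lagged covariance matrices
#'
#' Estimates `Gamma(k) = E[w_t w_{t-k}^T]` for `k = 0..max_lag` over the
#' overlapping part of the series, with divisor `T` (the Yule-Walker
#' convention, keeping the block-Toeplitz system positive semi-definite).
#'
#' @param x zero-mean series (`ts_set` or matrix).
#' @param max_lag largest lag.
#' @return an `m x m x (max_lag+1)` array; slice `k+1` holds `Gamma(k)`.
#' @export
estimate_covariances <- function(x, max_lag) {
  X <- as_ts_set(x)$data
  Tn <- nrow(X); m <- ncol(X)
  if (max_lag >= Tn) stop("max_lag must be smaller than the series length")
  G <- array(0, c(m, m, max_lag + 1L))
  for (k in 0:max_lag)
    G[, , k + 1L] <- crossprod(X[(k + 1):Tn, , drop = FALSE],
                               X[1:(Tn - k), , drop = FALSE]) / Tn
  G
}

# Block-Toeplitz Yule-Walker solve from a covariance array.
# Returns list(coef = m x m x p array with A_k in slice k, sigma_yw).
yw_solve <- function(G, p) {
  m <- dim(G)[1]
  GG <- matrix(0, m * p, m * p)
  C <- matrix(0, m, m * p)
  for (j in seq_len(p)) {
    C[, ((j - 1) * m + 1):(j * m)] <- G[, , j + 1L]
    for (k in seq_len(p)) {
      h <- k - j                       # block (j,k) = Gamma(k - j)
      blk <- if (h >= 0) G[, , h + 1L] else t(G[, , -h + 1L])
      GG[((j - 1) * m + 1):(j * m), ((k - 1) * m + 1):(k * m)] <- blk
    }
  }
  B <- tryCatch(t(solve(GG, t(C))), error = function(e) {
    warning("ill-conditioned Yule-Walker system; adding ridge jitter")
    ridge <- 1e-8 * mean(diag(GG))
    t(solve(GG + diag(ridge, nrow(GG)), t(C)))
  })
  A <- array(0, c(m, m, p))
  for (k in seq_len(p)) A[, , k] <- B[, ((k - 1) * m + 1):(k * m), drop = FALSE]
  list(coef = A, B = B)
}

# Residuals of a fitted VAR: rows p+1..T of X minus its lagged prediction.
var_residuals <- function(X, A) {
  Tn <- nrow(X); p <- dim(A)[3]
  R <- X[(p + 1):Tn, , drop = FALSE]
  for (k in seq_len(p))
    R <- R - X[(p + 1 - k):(Tn - k), , drop = FALSE] %*% t(A[, , k])
  R
}

#' Fit a vector autoregression by Yule-Walker
#'
#' Solves the block-Toeplitz Yule-Walker system built from the lagged
#' covariances `Gamma(0..p)`, then computes residuals by applying the fitted
#' regression to the data.  With `exclude` set, the named channel is removed
#' before fitting (the conditional auto-regression used by conditional GC).
#'
#' @param x zero-mean series (`ts_set` or matrix).
#' @param order regression order `p >= 1`.
#' @param exclude optional channel index to drop before fitting.
#' @param covs optional precomputed covariance array (from
#'   [estimate_covariances()] on the same data) to reuse across fits.
#' @return an object of class `var_fit`: `order`, `coefficients`
#'   (`m x m x p` array), `residuals` (`(T-p) x m`), `noise_cov`, `bic`,
#'   `excluded_channel`, `n_samples`.
#' @export
fit_var_yule_walker <- function(x, order, exclude = NULL, covs = NULL) {
  if (order < 1) stop("order must be >= 1")
  X <- as_ts_set(x)$data
  if (!is.null(exclude)) {
    X <- X[, -exclude, drop = FALSE]
    # covariances of a channel subset are the corresponding sub-blocks
    if (!is.null(covs)) covs <- covs[-exclude, -exclude, , drop = FALSE]
  }
  Tn <- nrow(X); m <- ncol(X)
  if (Tn <= m * order + 1) stop("series too short for this order")
  G <- covs %||% estimate_covariances(X, order)
  sol <- yw_solve(G, order)
  R <- var_residuals(X, sol$coef)
  Sig <- crossprod(R) / nrow(R)
  Tp <- Tn - order
  bic <- as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
    order * m^2 * log(Tp) / Tp
  structure(list(order = order, coefficients = sol$coef, residuals = R,
                 noise_cov = Sig, bic = bic, excluded_channel = exclude,
                 n_samples = Tn),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> order %d, %d channels, T = %d, BIC = %.4f\n",
              x$order, ncol(x$residuals), x$n_samples, x$bic))
  invisible(x)
}

#' Select the regression order by BIC
#'
#' Fits the full joint model at every order `1..max_order` and returns the
#' minimizer of `BIC(p) = ln det(Sigma_p) + p m^2 ln(T') / T'` with
#' `T' = T - p`; ties break toward the smaller order.
#'
#' @param x zero-mean series.
#' @param max_order largest order tried.
#' @return a list with `order` (the minimizer) and `bic` (the full curve).
#' @export
select_order_bic <- function(x, max_order = 30) {
  if (max_order < 1) stop("max_order must be >= 1")
  X <- as_ts_set(x)$data
  if (nrow(X) <= ncol(X) * max_order + 1)
    stop("series too short for max_order")
  G <- estimate_covariances(X, max_order)
  bic <- vapply(seq_len(max_order), function(p)
    fit_var_yule_walker(X, p, covs = G[, , 1:(p + 1), drop = FALSE])$bic,
    numeric(1))
  list(order = which.min(bic), bic = bic)
}

clip_gc <- function(f, tol = 1e-10) {
  if (any(f < -tol))
    warning(sprintf("negative GC estimate (%.3g) clipped to 0; possible model misspecification",
                    min(f)))
  pmax(f, 0)
}

#' Pairwise (bivariate) Granger causality
#'
#' `F_{y->x} = ln(var(eps_x^AR) / var(eps_x^JR))`: the log-ratio of the
#' autoregressive prediction-error variance of `x` on its own past to that of
#' the joint regression also using the past of `y`.  Tiny negative estimates
#' are clipped to zero.
#'
#' @param x,y equal-length zero-mean numeric vectors.
#' @param order regression order.
#' @return named vector `c(y_to_x, x_to_y)`.
#' @export
pairwise_gc <- function(x, y, order) {
  stopifnot(length(x) == length(y))
  ar_x <- fit_var_yule_walker(cbind(x), order)
  ar_y <- fit_var_yule_walker(cbind(y), order)
  jr <- fit_var_yule_walker(cbind(x, y), order)
  v <- unname(c(ar_x$noise_cov[1, 1], ar_y$noise_cov[1, 1]))
  vj <- unname(diag(jr$noise_cov))
  if (any(vj <= 0)) stop("zero joint residual variance: degenerate channel")
  clip_gc(c(y_to_x = log(v[1] / vj[1]), x_to_y = log(v[2] / vj[2])))
}

#' Conditional Granger-causality matrix
#'
#' One full m-channel joint fit gives, for every target i, the joint residual
#' variance `sigma_JR,i`; for each candidate source j, one (m-1)-channel fit
#' excluding j gives the conditional autoregressive variance
#' `sigma_AR,i|-j` for all i != j.  Then
#' `F[j, i] = ln(sigma_AR,i|-j / sigma_JR,i)`, the conditional GC from j to
#' i given all remaining channels; the diagonal is zero by definition.  The
#' order is selected once on the full joint model (BIC) and reused for every
#' conditional fit.
#'
#' @param x zero-mean series (`ts_set`, matrix, or `simulation_record`).
#' @param order regression order; `NULL` selects it by BIC.
#' @param max_order BIC search range when `order` is `NULL`.
#' @param mode label recorded in the result (`"voltage"` or
#'   `"spike_train"`).
#' @return an object of class `gc_matrix`: `values` (`m x m`, `[j, i]` is
#'   `F_{j->i}`), `order`, `n_samples`, `mode`, `conditional`, `bic_curve`.
#' @export
conditional_gc_matrix <- function(x, order = NULL, max_order = 30,
                                  mode = "voltage") {
  s <- as_ts_set(x)
  m <- ncol(s$data)
  if (m < 2) stop("need at least two channels")
  bic_curve <- NULL
  if (is.null(order)) {
    sel <- select_order_bic(s, max_order)
    order <- sel$order
    bic_curve <- sel$bic
  }
  G <- estimate_covariances(s, order)
  joint <- fit_var_yule_walker(s, order, covs = G)
  sigma_jr <- diag(joint$noise_cov)
  if (any(sigma_jr <= 0)) stop("zero joint residual variance")
  Fm <- matrix(0, m, m, dimnames = list(s$labels, s$labels))
  for (j in seq_len(m)) {
    fit_j <- fit_var_yule_walker(s, order, exclude = j, covs = G)
    sigma_ar <- rep(NA_real_, m)
    sigma_ar[-j] <- diag(fit_j$noise_cov)
    for (i in seq_len(m)[-j])
      Fm[j, i] <- log(sigma_ar[i] / sigma_jr[i])
  }
  off <- row(Fm) != col(Fm)
  Fm[off] <- clip_gc(Fm[off])
  diag(Fm) <- 0
  structure(list(values = Fm, order = order, n_samples = nrow(s$data),
                 mode = mode, conditional = TRUE, bic_curve = bic_curve,
                 joint_fit = joint),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("<gc_matrix> %d channels, order %d, T = %d, mode = %s\n",
              nrow(x$values), x$order, x$n_samples, x$mode))
  print(signif(x$values, 3))
  invisible(x)
}

#' Block-bootstrap standard errors of the conditional GC matrix
#'
#' Resamples whole blocks of consecutive samples (circular moving-block
#' bootstrap, preserving short-range temporal dependence), refits the
#' conditional GC at a fixed order, and returns the elementwise standard
#' deviation across replicates.
#'
#' @param x zero-mean series (`ts_set` or matrix).
#' @param order regression order (fixed across replicates).
#' @param n_boot number of bootstrap replicates.
#' @param block_len block length in samples (default 200, several times the
#'   synaptic correlation time at kHz sampling).
#' @param seed RNG seed.
#' @return an `m x m` matrix of bootstrap standard errors.
#' @export
gc_bootstrap_se <- function(x, order, n_boot = 30, block_len = 200, seed = 1) {
  s <- as_ts_set(x)
  X <- s$data
  Tn <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 404L))
  n_blocks <- ceiling(Tn / block_len)
  reps <- lapply(seq_len(n_boot), function(b) {
    starts <- sample.int(Tn, n_blocks, replace = TRUE)
    idx <- (rep(starts, each = block_len) +
              rep(seq_len(block_len) - 1L, n_blocks) - 1L) %% Tn + 1L
    idx <- idx[seq_len(Tn)]
    conditional_gc_matrix(X[idx, , drop = FALSE], order = order)$values
  })
  arr <- simplify2array(reps)
  apply(arr, c(1, 2), sd)
}

#' Chi-squared significance threshold for estimated GC
#'
#' Under the null of no causal influence, `T * F_hat` is asymptotically
#' chi-squared with `p` degrees of freedom (p = regression order), so the
#' threshold at level `alpha` is `qchisq(1 - alpha, p) / T`.  Optionally
#' Bonferroni-corrects across the `m (m - 1)` directed pairs.
#'
#' @param gc a `gc_matrix` (supplies `order` and `n_samples`), or a list
#'   with those two fields.
#' @param alpha significance level in (0, 1).
#' @param bonferroni apply Bonferroni correction across directed pairs.
#' @return the threshold on the GC scale.
#' @export
gc_significance_threshold <- function(gc, alpha = 0.01, bonferroni = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  a <- alpha
  if (bonferroni) {
    m <- nrow(gc$values)
    a <- alpha / (m * (m - 1))
  }
  qchisq(1 - a, df = gc$order) / gc$n_samples
}
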