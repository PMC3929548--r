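# Stationary VAR fixtures with analytically known Granger causality, used as
# simulation oracles for the estimation machinery.

# Exact autocovariances Gamma(0..max_lag) of a stationary VAR(p) process,
# via the companion-form discrete Lyapunov equation solved by vectorization.
var_population_autocov <- function(coef, noise_cov, max_lag) {
  m <- dim(coef)[1]; p <- dim(coef)[3]
  Fc <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) Fc[1:m, ((k - 1) * m + 1):(k * m)] <- coef[, , k]
  if (p > 1)
    Fc[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  if (max(Mod(eigen(Fc, only.values = TRUE)$values)) >= 1)
    stop("non-stationary VAR coefficients")
  Q <- matrix(0, m * p, m * p)
  Q[1:m, 1:m] <- noise_cov
  vecP <- solve(diag((m * p)^2) - kronecker(Fc, Fc), as.vector(Q))
  P <- matrix(vecP, m * p, m * p)
  G <- array(0, c(m, m, max_lag + 1L))
  for (k in 0:min(max_lag, p - 1))
    G[, , k + 1L] <- P[1:m, (k * m + 1):((k + 1) * m)]
  if (max_lag >= p) {
    for (k in p:max_lag) {
      S <- matrix(0, m, m)
      for (j in seq_len(p)) S <- S + coef[, , j] %*% G[, , k - j + 1L]
      G[, , k + 1L] <- S
    }
  }
  G
}

# Population residual covariance of an order-q Yule-Walker regression on a
# channel subset, computed from exact autocovariances.
pop_yw_sigma <- function(G, channels, q) {
  Gs <- G[channels, channels, , drop = FALSE]
  sol <- yw_solve(Gs, q)
  m <- length(channels)
  S <- Gs[, , 1L]
  for (k in seq_len(q))
    S <- S - matrix(sol$coef[, , k], m, m) %*% t(matrix(Gs[, , k + 1L], m, m))
  # symmetrize against roundoff
  (S + t(S)) / 2
}

#' Analytic conditional GC of a VAR model
#'
#' Computes, from the exact process autocovariances, the population
#' conditional GC matrix that a Yule-Walker estimator of order `order`
#' converges to: `F[j, i] = ln(sigma_AR,i|-j / sigma_JR,i)` with both
#' residual variances taken from population order-`order` regressions.
#'
#' @param coef `m x m x p` coefficient array.
#' @param noise_cov innovation covariance.
#' @param order evaluation order (defaults to the model order; the joint
#'   regression is then exact).
#' @return `m x m` matrix of analytic conditional GC values.
#' @export
analytic_gc_matrix <- function(coef, noise_cov, order = dim(coef)[3]) {
  m <- dim(coef)[1]
  G <- var_population_autocov(coef, noise_cov, order)
  sigma_jr <- diag(pop_yw_sigma(G, seq_len(m), order))
  Fm <- matrix(0, m, m)
  for (j in seq_len(m)) {
    sig <- diag(pop_yw_sigma(G, seq_len(m)[-j], order))
    Fm[j, seq_len(m)[-j]] <- log(sig / sigma_jr[-j])
  }
  pmax(Fm, 0)
}

#' Generate a stationary VAR fixture with known analytic GC
#'
#' Samples random stationary coefficient matrices (rejection sampling until
#' the companion spectral radius is below 0.95), optionally imposing a
#' directed coupling pattern, and returns the exact analytic conditional GC
#' together with a simulated realization.
#'
#' @param m dimension.
#' @param p model order.
#' @param T_sim length of the simulated realization.
#' @param coupling_pattern optional 0/1 `m x m` matrix; `[j, i] = 0` forces
#'   all lag coefficients of channel j in channel i's equation to zero
#'   (diagonal ignored).
#' @param seed integer seed.
#' @param scale typical coefficient magnitude before stabilization.
#' @param max_tries rejection-sampling budget.
#' @return an object of class `var_fixture`: `coef`, `noise_cov`,
#'   `analytic_gc`, `series` (`T_sim x m` matrix), `order`, `seed`.
#' @export
generate_var_fixture <- function(m = 2, p = 2, T_sim = 1e5,
                                 coupling_pattern = NULL, seed = 1,
                                 scale = 0.3, max_tries = 200) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 31L))
  mask <- matrix(TRUE, m, m)
  if (!is.null(coupling_pattern)) {
    mask <- coupling_pattern != 0 | diag(m) == 1
  }
  coef <- NULL
  for (try in seq_len(max_tries)) {
    A <- array(rnorm(m * m * p, sd = scale / sqrt(p)), c(m, m, p))
    for (k in seq_len(p)) {
      A[, , k][t(!mask)] <- 0   # A[,,k][i,j] multiplies channel j in eq. i
      diag(A[, , k]) <- diag(A[, , k]) + 0.5 / p
    }
    Fc <- matrix(0, m * p, m * p)
    for (k in seq_len(p)) Fc[1:m, ((k - 1) * m + 1):(k * m)] <- A[, , k]
    if (p > 1) Fc[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
    if (max(Mod(eigen(Fc, only.values = TRUE)$values)) < 0.95) {
      coef <- A
      break
    }
  }
  if (is.null(coef)) stop("could not sample a stable coefficient set")
  noise_cov <- diag(m)
  burn <- 200 + 10 * p
  Tn <- T_sim + burn
  E <- matrix(rnorm(Tn * m), Tn, m)
  X <- matrix(0, Tn, m)
  for (t in (p + 1):Tn) {
    acc <- E[t, ]
    for (k in seq_len(p)) acc <- acc + coef[, , k] %*% X[t - k, ]
    X[t, ] <- acc
  }
  structure(list(coef = coef, noise_cov = noise_cov,
                 analytic_gc = analytic_gc_matrix(coef, noise_cov),
                 series = X[(burn + 1):Tn, , drop = FALSE],
                 order = p, seed = seed),
            class = "var_fixture")
}

#' @export
print.var_fixture <- function(x, ...) {
  cat(sprintf("<var_fixture> VAR(%d), %d channels, T = %d\n",
              x$order, dim(x$coef)[1], nrow(x$series)))
  invisible(x)
}
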