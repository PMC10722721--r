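# Internal numerical helpers shared across the MCMC and WAIC code.

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# log(mean(exp(x))) with log-sum-exp stabilisation; x a numeric vector.
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Row-wise log(mean(exp())) for a draws matrix (rows = observations).
row_log_mean_exp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowMeans(exp(x - m)))
}

# Sample variance per row (denominator n - 1), vectorised.
row_var <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

`%||%` <- rlang::`%||%`

stopifnot_scalar_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.")
  }
  as.integer(seed)
}

# Autocorrelation-based effective sample size (initial positive sequence
# estimator on pairwise sums, as used for MCMC output analysis).
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(if (sd(x) == 0) 1 else n)
  ac <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                   demean = TRUE)$acf[, 1L, 1L]
  # sum paired autocorrelations while the pair sum stays positive
  rho_sum <- 0
  k <- 2L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    rho_sum <- rho_sum + pair
    k <- k + 2L
  }
  ess <- n / (1 + 2 * rho_sum)
  max(1, min(ess, n))
}

# Geweke convergence z-score: compare means of the first `frac1` and last
# `frac2` fractions of the chain using spectral-density-free SEs (batch SEs).
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  se <- function(v) {
    ess <- ess_autocorr(v)
    sd(v) / sqrt(ess)
  }
  denom <- sqrt(se(a)^2 + se(b)^2)
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}
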