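# Internal MCMC utilities shared by the MANOVA and dynamics samplers:
# log-sum-exp, multinomial log-pmf, inverse-Wishart draws, split R-hat,
# effective sample size, HPD intervals, and the generalized-Pareto tail fit
# used by PSIS.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# multinomial log-pmf with full combinatorial constant; y and p vectors
mult_logpmf <- function(y, p) {
  lgamma(sum(y) + 1) - sum(lgamma(y + 1)) + sum(y * log(p))
}

# rows of Y against rows of P
mult_logpmf_rows <- function(Y, P) {
  lgamma(rowSums(Y) + 1) - rowSums(lgamma(Y + 1)) + rowSums(Y * log(P))
}

# inverse-Wishart draw via base rWishart on the inverse scale
rinvwishart <- function(nu, S) {
  W <- rWishart(1L, nu, solve(S))[, , 1]
  solve(W)
}

# split R-hat (rank-normalization omitted; chains are long and targets smooth)
split_rhat <- function(x, chains) {
  draws <- matrix(x, ncol = chains)
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  B <- nn * var(mu)
  W <- mean(apply(sub, 2, var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size by initial positive sequence of autocorrelations
ess_basic <- function(x, chains) {
  draws <- matrix(x, ncol = chains)
  n <- nrow(draws)
  if (var(as.vector(draws)) == 0) return(length(x))
  rho <- sapply(seq_len(ncol(draws)), function(j) {
    a <- acf(draws[, j], lag.max = min(n - 1L, 200L), plot = FALSE)$acf[, 1, 1]
    a
  })
  rho <- rowMeans(rho)
  s <- 0
  for (k in seq(2, length(rho))) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  max(1, length(x) / (1 + 2 * s))
}

#' Highest-posterior-density interval of a sample
#'
#' Shortest interval containing the requested fraction of the draws.
#' @param x numeric sample.
#' @param level interval mass (default 0.95).
#' @return named vector (lower, upper).
#' @export
hpd_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + k])
}

# Generalized Pareto fit (location mu fixed) by the Zhang & Stephens (2009)
# posterior-mean method; returns shape k and scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  # ties at the cutoff (duplicated MCMC draws) give zero exceedances; the
  # tail fit is then undefined and smoothing is skipped
  if (n < 5L || x[n] <= 0 || x[ceiling(n / 4 + 0.5)] <= 0)
    return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / prior_bs / x[ceiling(n / 4 + 0.5)]
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  L <- n * (log(bs / ks) + ks - 1)
  w <- exp(L - logsumexp(L))
  b <- sum(bs * w)
  k <- -mean(log1p(-b * x))
  list(k = k, sigma = k / b)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights from log importance ratios.
# Returns list(log_weights (normalized to max 0 before smoothing scale),
# khat). Algorithm follows the PSIS recipe: fit a generalized Pareto to the
# largest M = min(0.2 S, 3 sqrt(S)) ratios above the cutoff, replace them by
# expected order statistics of the fitted tail, truncate at the raw maximum.
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5L || S < 25L) return(list(log_weights = lw, khat = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(log_weights = lw, khat = fit$k))
  p <- (seq_len(M) - 0.5) / M
  smoothed <- log(exp(cutoff) + qgpd(p, fit$k, fit$sigma))
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
  list(log_weights = lw, khat = fit$k)
}
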