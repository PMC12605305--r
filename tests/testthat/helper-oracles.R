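# Independent oracles used across the suite. Each is deliberately naive
# (enumeration, brute force, textbook iterations) and shares no code with the
# package internals it checks.

# Exact distribution of O = sum of independent Bernoulli(p_i): dynamic
# programming convolution. Returns P(O = k) for k = 0..n.
poisbinom_pmf <- function(p) {
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}

# Exact mean/variance of log(O/E) conditional on O >= 1 (population
# variance, the limit of a sample variance over replicates).
enum_logsir_moments <- function(p, E) {
  pmf <- poisbinom_pmf(p)
  n <- length(p)
  w <- pmf[-1] / sum(pmf[-1])
  v <- log(seq_len(n) / E)
  m <- sum(w * v)
  list(mean = m, var = sum(w * (v - m)^2), p_zero = pmf[1])
}

# Plain logistic regression by hand-rolled Newton iterations.
newton_logistic <- function(X, y, iter = 50, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- drop(crossprod(X, y - p))
    H <- crossprod(X * W, X)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, cov = solve(H))
}

# Brute-force trapezoid integration of E[plogis(eta + u)], u ~ N(0, sigma2).
trapz_marginal <- function(eta, sigma2, n_grid = 200000L, span = 8) {
  s <- sqrt(sigma2)
  u <- seq(-span * s, span * s, length.out = n_grid)
  f <- stats::plogis(eta + u) * stats::dnorm(u, 0, s)
  sum((f[-1] + f[-n_grid]) / 2 * diff(u))
}

# O(n^2) double-loop versions of the delta-method component formulas.
loop_var_observed <- function(p, sigma_u2) {
  a <- p * (1 - p)
  s <- sum(a)
  n <- length(p)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + 2 * a[i] * a[j] * sigma_u2
  s
}
loop_var_expected <- function(p, var_eta, sigma_u2) {
  a <- p * (1 - p)
  s <- sum(a^2 * var_eta)
  n <- length(p)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + 2 * a[i] * a[j] * sigma_u2
  s
}
loop_cov_obs_exp <- function(p, var_eta, sigma_u2) {
  a <- p * (1 - p)
  s <- sum(a * var_eta)
  n <- length(p)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + 2 * a[i] * a[j] * sigma_u2
  s
}
loop_sqrt_variant <- function(p, diag_term, sigma_u2) {
  a <- p * (1 - p)
  s <- diag_term
  n <- length(p)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + 2 * sqrt(a[i] * a[j]) * sigma_u2
  s
}

# Standard error of a sample variance from the fourth central moment
# (used for replication-consistency bands between independent runs).
var_of_sample_var_se <- function(x, ess = length(x)) {
  x <- x[!is.na(x)]
  m4 <- mean((x - mean(x))^4)
  v <- stats::var(x)
  sqrt(max(m4 - v^2, 0) / ess)
}
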