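#' Bayesian sampler configuration
#'
#' Defaults follow registry-scale practice: 25,500 iterations per chain with
#' 500 burn-in, 3 chains, thinning 1, weakly informative independent
#' `N(0, 100)` priors on every coefficient and a `Gamma(0.001, 0.001)` prior
#' on the random-intercept precision `tau` (`sigma_u2 = 1/tau`).
#'
#' @param iterations iterations per chain including burn-in (default 25500).
#' @param burn_in burn-in iterations (default 500; must be `< iterations`).
#' @param chains number of chains (default 3).
#' @param thin thinning interval (default 1).
#' @param prior_beta_mean scalar or vector prior mean for the coefficients.
#' @param prior_beta_var scalar or vector prior variance (diagonal), `> 0`.
#' @param prior_tau_shape,prior_tau_rate Gamma prior parameters for `tau`.
#' @param seed integer seed; chain `k` uses a seed derived from it.
#' @return an object of class `bayes_config`.
#' @export
bayes_config <- function(iterations = 25500L, burn_in = 500L, chains = 3L,
                         thin = 1L, prior_beta_mean = 0, prior_beta_var = 100,
                         prior_tau_shape = 0.001, prior_tau_rate = 0.001,
                         seed = 1L) {
  if (iterations <= burn_in) stop("`iterations` must exceed `burn_in`", call. = FALSE)
  if (chains < 1L) stop("`chains` must be >= 1", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  if (any(prior_beta_var <= 0)) stop("`prior_beta_var` must be > 0", call. = FALSE)
  if (prior_tau_shape <= 0 || prior_tau_rate <= 0)
    stop("Gamma prior parameters must be > 0", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), chains = as.integer(chains),
                 thin = as.integer(thin),
                 prior_beta_mean = prior_beta_mean,
                 prior_beta_var = prior_beta_var,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_rate = prior_tau_rate,
                 seed = as.integer(seed)),
            class = "bayes_config")
}

#' Sample the posterior of the hierarchical logistic model
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler (block random-walk for
#' the coefficients, per-center random walk for the intercepts, conjugate
#' Gamma step for the precision, plus prior independence proposals) targeting
#' the posterior of `beta`, `u_1..u_C` and `tau` under Bernoulli likelihood,
#' Gaussian coefficient priors and a Gamma precision prior. Split-R-hat and
#' effective sample sizes are computed for every coefficient and for
#' `sigma_u2`; any R-hat above 1.05 flags the result non-converged (returned
#' with a warning, never silently trusted).
#'
#' @param cohort cohort data.frame, or `NULL` for the prior-only (no-data)
#'   model, in which case `n_coef` and `n_centers` give the dimensions.
#' @param spec a [model_spec()] (ignored when `cohort` is `NULL`).
#' @param config a [bayes_config()].
#' @param n_coef,n_centers dimensions for the prior-only model.
#' @return an object of class `posterior_draws`: matrices `beta`
#'   (draws x coefficients), `u`, vectors `tau`, `sigma_u2`, a `chain` index,
#'   a `diagnostics` data.frame (`param`, `rhat`, `ess`), `converged`, and
#'   the data-side objects (`X`, `center_idx`, `O`, `center_labels`) needed
#'   by [posterior_log_sir()].
#' @export
sample_posterior <- function(cohort, spec = NULL, config = bayes_config(),
                             n_coef = 1L, n_centers = 2L) {
  stopifnot(inherits(config, "bayes_config"))
  if (!is.null(cohort)) {
    stopifnot(inherits(spec, "model_spec"))
    d <- spec_factors(cohort, spec)
    X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs(spec))),
                             data = d)
    y <- as.integer(cohort[[spec$outcome]])
    labels <- unique(as.character(cohort[[spec$group]]))
    center_idx <- match(as.character(cohort[[spec$group]]), labels)
    O <- as.numeric(rowsum(as.numeric(y), center_idx))
  } else {
    X <- matrix(numeric(0), nrow = 0, ncol = n_coef,
                dimnames = list(NULL, paste0("b", seq_len(n_coef))))
    y <- integer(0)
    labels <- sprintf("C%02d", seq_len(n_centers))
    center_idx <- integer(0)
    O <- rep(NA_real_, n_centers)
  }
  p <- ncol(X)
  C <- length(labels)
  mu <- rep_len(config$prior_beta_mean, p)
  v <- rep_len(config$prior_beta_var, p)

  # initial value and proposal shape: penalized logistic curvature when data
  # are present, the prior covariance otherwise
  if (nrow(X) > 0) {
    g <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    beta_init <- ifelse(is.finite(g$coefficients), g$coefficients, 0)
    pr <- stats::plogis(drop(X %*% beta_init))
    W <- pr * (1 - pr)
    H <- crossprod(X * sqrt(W)) + diag(1 / v, p)
    V <- tryCatch(solve(H), error = function(e) diag(v, p))
  } else {
    beta_init <- mu
    V <- diag(v, p)
  }
  L <- t(chol((V + t(V)) / 2))

  n_keep <- (config$iterations - config$burn_in) %/% config$thin
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed((config$seed + 10007L * (ch - 1L)) %% 2147483647L)
    chains[[ch]] <- .logit_mwg_chain(
      X, y, as.integer(center_idx), C,
      as.numeric(beta_init), L, mu, v,
      config$prior_tau_shape, config$prior_tau_rate,
      config$iterations, config$burn_in, config$thin)
  }

  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- colnames(X)
  u <- do.call(rbind, lapply(chains, `[[`, "u"))
  colnames(u) <- labels
  tau <- unlist(lapply(chains, `[[`, "tau"), use.names = FALSE)
  chain_id <- rep(seq_len(config$chains), each = n_keep)

  diag_mat <- cbind(beta, sigma_u2 = 1 / tau)
  diags <- data.frame(
    param = colnames(diag_mat),
    rhat = apply(diag_mat, 2, function(x) split_rhat(x, chain_id)),
    ess = apply(diag_mat, 2, function(x) ess_mcmc(x, chain_id)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  converged <- all(is.na(diags$rhat) | diags$rhat <= 1.05)
  if (!converged)
    warning("MCMC did not converge by split R-hat <= 1.05; result flagged",
            call. = FALSE)

  structure(list(
    beta = beta, u = u, tau = tau, sigma_u2 = 1 / tau, chain = chain_id,
    diagnostics = diags, converged = converged,
    accept_beta = vapply(chains, `[[`, numeric(1), "accept_beta"),
    config = config, X = X, center_idx = center_idx, O = O,
    center_labels = labels
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %d kept draws x %d chains, %d coefficients, %d centers\n",
              nrow(x$beta) / max(x$chain), max(x$chain), ncol(x$beta),
              length(x$center_labels)))
  cat(sprintf("  converged = %s (max R-hat %.3f), median sigma_u2 = %.4f\n",
              x$converged, max(x$diagnostics$rhat, na.rm = TRUE),
              stats::median(x$sigma_u2)))
  invisible(x)
}

#' Posterior summaries of each center's Log-SIR
#'
#' For each retained draw `(beta, sigma_u2)` the center's expected count is
#' recomputed under the marginal convention (random intercept integrated out
#' by 41-node Gauss-Hermite quadrature) and `Log-SIR_c = log(O_c / E_c)` is
#' evaluated with the observed count held fixed. Summaries are taken over
#' all draws: posterior mean, variance (`S - 1` denominator) and type-7
#' 2.5% / 97.5% quantiles.
#'
#' @param draws a [sample_posterior()] result (data-based).
#' @param level credible level (default 0.95).
#' @param force proceed even if the sampler is flagged non-converged.
#' @return data.frame of class `variance_estimate` with columns `center_id`,
#'   `method` (`"bayes"`), `n`, `O`, `E` (posterior mean), `log_sir`
#'   (posterior mean), `var`, `se`, `lcri`, `ucri`. Centers with `O = 0`
#'   are flagged undefined (`NA` summaries). The per-draw Log-SIR matrix is
#'   attached as attribute `"draws"`.
#' @export
posterior_log_sir <- function(draws, level = 0.95, force = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (nrow(draws$X) == 0)
    stop("posterior_log_sir needs a data-based posterior", call. = FALSE)
  if (!draws$converged && !force)
    stop("sampler flagged non-converged; rerun longer or pass force = TRUE",
         call. = FALSE)

  # collapse identical (covariate pattern, center) rows before the per-draw
  # quadrature pass
  key <- do.call(paste, c(as.data.frame(draws$X), list(draws$center_idx)))
  first <- !duplicated(key)
  map <- match(key, key[first])
  wt <- as.numeric(tabulate(map, sum(first)))
  Xu <- draws$X[first, , drop = FALSE]
  cu <- draws$center_idx[first]

  r <- gh_rule(41L)
  E_draws <- .center_expected_draws(Xu, wt, as.integer(cu),
                                    length(draws$center_labels),
                                    draws$beta, draws$sigma_u2, r$z, r$w)
  O <- draws$O
  C <- length(O)
  S <- nrow(E_draws)
  ls_draws <- matrix(NA_real_, S, C, dimnames = list(NULL, draws$center_labels))
  for (c in seq_len(C)) {
    if (!is.na(O[c]) && O[c] > 0) ls_draws[, c] <- log(O[c] / E_draws[, c])
  }
  defined <- !is.na(ls_draws[1, ])
  if (any(!defined))
    warning(sprintf("O = 0 for center(s) %s; no posterior summaries",
                    paste(draws$center_labels[!defined], collapse = ", ")),
            call. = FALSE)

  alpha <- (1 - level) / 2
  mean_ls <- colMeans(ls_draws)
  var_ls <- apply(ls_draws, 2, stats::var)
  qs <- apply(ls_draws, 2, function(d) {
    if (anyNA(d)) return(c(NA_real_, NA_real_))
    stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 7)
  })
  n_per <- as.integer(tabulate(draws$center_idx, C))

  out <- structure(data.frame(
    center_id = draws$center_labels, method = "bayes",
    n = n_per, O = O, E = colMeans(E_draws),
    log_sir = mean_ls, var = var_ls, se = sqrt(var_ls),
    lcri = qs[1, ], ucri = qs[2, ], stringsAsFactors = FALSE
  ), class = c("variance_estimate", "data.frame"))
  attr(out, "draws") <- ls_draws
  out
}

#' Persist posterior draws
#'
#' Writes the draws as a rectangular CSV (one row per kept draw) with a JSON
#' sidecar holding the configuration and convergence diagnostics.
#'
#' @param draws a `posterior_draws` object.
#' @param csv_path,json_path output paths.
#' @export
write_posterior_draws <- function(draws, csv_path, json_path) {
  d <- data.frame(chain = draws$chain, draws$beta, draws$u,
                  tau = draws$tau, sigma_u2 = draws$sigma_u2,
                  check.names = FALSE)
  utils::write.csv(d, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    config = unclass(draws$config),
    diagnostics = draws$diagnostics,
    converged = draws$converged,
    accept_beta = draws$accept_beta
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

# ---- chain diagnostics ----------------------------------------------------

# split R-hat: each chain halved, then the usual between/within ratio
split_rhat <- function(x, chain_id) {
  halves <- split_chain_halves(x, chain_id)
  n <- min(lengths(halves))
  if (n < 4L) return(NA_real_)
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || !is.finite(B)) return(NA_real_)
  if (W <= 0) return(if (isTRUE(stats::var(x) == 0)) NA_real_ else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size with Geyer initial-positive-pair truncation
ess_mcmc <- function(x, chain_id) {
  halves <- split_chain_halves(x, chain_id)
  n <- min(lengths(halves))
  if (n < 8L) return(NA_real_)
  halves <- lapply(halves, function(h) h[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  varplus <- (n - 1) / n * W + stats::var(means)
  if (!is.finite(varplus) || varplus <= 0) return(NA_real_)
  max_lag <- min(n - 1L, 1000L)
  acovs <- vapply(halves, function(h) {
    stats::acf(h, lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acovs)) / varplus
  # sum paired autocorrelations while the pair sums stay positive
  s <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * s)  # s sums rho at lags >= 1 in positive pairs
  max(1, min(ess, m * n))
}

split_chain_halves <- function(x, chain_id) {
  out <- list()
  for (ch in unique(chain_id)) {
    v <- x[chain_id == ch]
    h <- length(v) %/% 2L
    if (h < 2L) next
    out <- c(out, list(v[seq_len(h)], v[(h + 1L):(2L * h)]))
  }
  out
}
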