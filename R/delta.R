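# Analytic (delta-method) variance of the per-center Log-SIR under the
# random-intercept logistic model. All pairwise sums use the closed-form
# identity 2 * sum_{i<j} a_i b_j = (sum a)(sum b) - sum(a b) for a == b,
# giving O(n) evaluation of the O(n^2) displays.

pairwise_sum2 <- function(a) sum(a)^2 - sum(a * a)

#' Variance of the observed count O_c
#'
#' `Var(O_c) = sum p_i(1-p_i) + 2 sum_{i<j} p_i(1-p_i) p_j(1-p_j) sigma_u2`:
#' Bernoulli variances plus the pairwise covariance induced by the shared
#' center random effect.
#'
#' @param p per-patient probabilities in one center, strictly in (0, 1).
#' @param sigma_u2 random-intercept variance, `>= 0`.
#' @param pairwise `"product"` uses the covariance exactly as above;
#'   `"sqrt"` replaces each pairwise factor `p_i(1-p_i) p_j(1-p_j)` with its
#'   square root (sensitivity variant, see the methods vignette).
#' @return a single number.
#' @export
var_observed <- function(p, sigma_u2, pairwise = c("product", "sqrt")) {
  pairwise <- match.arg(pairwise)
  check_delta_inputs(p, sigma_u2)
  a <- p * (1 - p)
  b <- if (pairwise == "sqrt") sqrt(a) else a
  sum(a) + sigma_u2 * pairwise_sum2(b)
}

#' Variance of the expected count E_c
#'
#' `Var(E_c) = sum [p_i(1-p_i)]^2 Var(eta_i)
#'  + 2 sum_{i<j} [p_i(1-p_i)][p_j(1-p_j)] sigma_u2`: the first-order
#' propagation of linear-predictor uncertainty through the inverse logit,
#' with pairwise terms from the shared random effect
#' (`Cov(eta_i, eta_j) = sigma_u2`).
#'
#' @param p per-patient probabilities in one center.
#' @param var_eta per-patient `Var(eta_i)` (same length as `p`, `>= 0`).
#' @inheritParams var_observed
#' @return a single number.
#' @export
var_expected <- function(p, var_eta, sigma_u2,
                         pairwise = c("product", "sqrt")) {
  pairwise <- match.arg(pairwise)
  check_delta_inputs(p, sigma_u2, var_eta)
  a <- p * (1 - p)
  b <- if (pairwise == "sqrt") sqrt(a) else a
  sum(a^2 * var_eta) + sigma_u2 * pairwise_sum2(b)
}

#' Covariance of O_c and E_c
#'
#' `Cov(O_c, E_c) = sum p_i(1-p_i) Var(eta_i)
#'  + 2 sum_{i<j} p_i(1-p_i) p_j(1-p_j) sigma_u2`: observed and expected
#' counts co-move because both depend on the same underlying probabilities.
#'
#' @inheritParams var_expected
#' @return a single number.
#' @export
cov_obs_exp <- function(p, var_eta, sigma_u2,
                        pairwise = c("product", "sqrt")) {
  pairwise <- match.arg(pairwise)
  check_delta_inputs(p, sigma_u2, var_eta)
  a <- p * (1 - p)
  b <- if (pairwise == "sqrt") sqrt(a) else a
  sum(a * var_eta) + sigma_u2 * pairwise_sum2(b)
}

check_delta_inputs <- function(p, sigma_u2, var_eta = NULL) {
  if (!length(p)) stop("`p` must be non-empty", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  assert_scalar_number(sigma_u2, "sigma_u2", lower = 0)
  if (!is.null(var_eta)) {
    if (length(var_eta) != length(p))
      stop("`var_eta` must have the same length as `p`", call. = FALSE)
    if (any(var_eta < 0)) stop("`var_eta` must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' First-order variance of a center's Log-SIR
#'
#' `Var(Log-SIR_c) ~ Var(O)/O^2 + Var(E)/E^2 - 2 Cov(O,E)/(O E)`, the delta
#' method applied to `g(O, E) = log(O/E)` with gradient `(1/O, -1/E)`. The
#' first-order value can be negative (it is an approximation, not a
#' quadratic form); it is floored at 0 with a warning.
#'
#' @param O observed count (`> 0`).
#' @param E expected count (`> 0`).
#' @param var_O,var_E,cov_OE the covariance components (see
#'   [var_observed()], [var_expected()], [cov_obs_exp()]).
#' @return list with `var` (floored) and `se`.
#' @export
var_log_sir_delta <- function(O, E, var_O, var_E, cov_OE) {
  if (!(O > 0)) stop("O must be > 0 (undefined Log-SIR)", call. = FALSE)
  if (!(E > 0)) stop("E must be > 0", call. = FALSE)
  v <- var_O / O^2 + var_E / E^2 - 2 * cov_OE / (O * E)
  if (v < 0) {
    warning(sprintf(
      "negative first-order variance (%.3g) floored at 0", v), call. = FALSE)
    v <- 0
  }
  list(var = v, se = sqrt(v))
}

#' Delta-method variance estimates for every center
#'
#' Applies the analytic formula per center using the marginal predicted
#' probabilities from the fit (the same probabilities that define `E_c`).
#' By default `Var(eta_i) = sigma_u2_hat`, matching the algebra in which the
#' fixed effects are treated as known; `var_eta_mode = "plus_fixed"` adds the
#' fixed-effect estimation terms `x_i' cov_beta x_j` to both the diagonal and
#' the pairwise sums for sensitivity analysis.
#'
#' @param fit a [fit_glmm()] result.
#' @param cohort the cohort the fit was computed on.
#' @param summary optional precomputed [summarize_centers()] result (marginal
#'   convention); computed if omitted.
#' @param var_eta_mode `"sigma_u2"` (default) or `"plus_fixed"`.
#' @param pairwise see [var_observed()].
#' @param level confidence level for the Wald interval columns.
#' @return data.frame of class `variance_estimate` with columns `center_id`,
#'   `method` (`"delta"`), `n`, `O`, `E`, `log_sir`, `var`, `se`, `lci`,
#'   `uci`. Centers with undefined Log-SIR carry `NA` variance columns.
#' @export
delta_variance <- function(fit, cohort, summary = NULL,
                           var_eta_mode = c("sigma_u2", "plus_fixed"),
                           pairwise = c("product", "sqrt"), level = 0.95) {
  var_eta_mode <- match.arg(var_eta_mode)
  pairwise <- match.arg(pairwise)
  stopifnot(inherits(fit, "glmm_fit"))
  p_marg <- predict_probabilities(fit, mode = "marginal")
  if (is.null(summary)) summary <- summarize_centers(cohort, p_marg)
  s2 <- fit$sigma_u2_hat

  C <- nrow(summary)
  out_var <- rep(NA_real_, C)
  for (c in seq_len(C)) {
    rows <- which(fit$center_idx == c)
    p <- p_marg[rows]
    a <- p * (1 - p)
    if (var_eta_mode == "sigma_u2") {
      var_eta <- rep(s2, length(p))
      vO <- var_observed(p, s2, pairwise)
      vE <- var_expected(p, var_eta, s2, pairwise)
      cOE <- cov_obs_exp(p, var_eta, s2, pairwise)
    } else {
      X <- fit$X[rows, , drop = FALSE]
      var_eta <- s2 + rowSums((X %*% fit$cov_beta) * X)
      # pairwise fixed-effect term: sum_{i != j} a_i a_j x_i' V x_j
      M <- drop(crossprod(X, a))
      fixed_pair <- drop(t(M) %*% fit$cov_beta %*% M) -
        sum(a^2 * rowSums((X %*% fit$cov_beta) * X))
      vO <- var_observed(p, s2, pairwise)
      vE <- var_expected(p, var_eta, s2, pairwise) + fixed_pair
      cOE <- cov_obs_exp(p, var_eta, s2, pairwise) + fixed_pair
    }
    if (isTRUE(summary$defined[c])) {
      out_var[c] <- var_log_sir_delta(summary$O[c], summary$E[c],
                                      vO, vE, cOE)$var
    }
  }
  se <- sqrt(out_var)
  ci <- wald_interval(summary$log_sir, se, level)
  structure(data.frame(
    center_id = summary$center_id, method = "delta",
    n = summary$n, O = summary$O, E = summary$E,
    log_sir = summary$log_sir, var = out_var, se = se,
    lci = ci$lower, uci = ci$upper, stringsAsFactors = FALSE
  ), class = c("variance_estimate", "data.frame"))
}

#' Write a per-center variance estimate CSV
#'
#' Columns `center_id,method,log_sir,var,se` plus any interval columns
#' present (`lci,uci`, bootstrap `n_undefined`, Bayesian `lcri,ucri`).
#'
#' @param est a `variance_estimate` data.frame.
#' @param path output path.
#' @export
write_variance_estimate <- function(est, path) {
  keep <- intersect(c("center_id", "method", "n", "O", "E", "log_sir",
                      "var", "se", "lci", "uci", "lcri", "ucri",
                      "n_undefined"), names(est))
  utils::write.csv(est[, keep], path, row.names = FALSE)
  invisible(path)
}
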