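#' @useDynLib sirvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rbinom plogis qlogis qnorm quantile var acf
#'   model.matrix as.formula setNames logLik median cor glm binomial coef vcov
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse logit and logit
#'
#' Thin wrappers over [stats::plogis()] and [stats::qlogis()], exported so the
#' link used throughout the package is named explicitly.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @export
logit <- function(x) stats::qlogis(x)

# Gauss-Hermite rule for E_u[f(u)], u ~ N(0, sigma2), cached per node count.
# Returns list(z, w) with sum(w) == 1 and z already scaled to N(0,1) abscissas.
gh_rule <- local({
  cache <- list()
  function(nodes = 41L) {
    key <- as.character(nodes)
    if (is.null(cache[[key]])) {
      gh <- pracma::gaussHermite(nodes)
      cache[[key]] <<- list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
    }
    cache[[key]]
  }
})

#' Marginal (population-averaged) inverse-logit mean
#'
#' Computes `E[plogis(eta + u)]` with `u ~ N(0, sigma2)` by Gauss-Hermite
#' quadrature. This is the marginal success probability used for expected
#' counts under indirect standardization: a center's own random effect is
#' integrated out rather than plugged in.
#'
#' @param eta numeric vector of linear predictors (fixed-effect part).
#' @param sigma2 random-intercept variance (scalar, `>= 0`).
#' @param nodes number of quadrature nodes (default 41).
#' @return numeric vector of probabilities in (0, 1).
#' @export
marginal_invlogit <- function(eta, sigma2, nodes = 41L) {
  stopifnot(length(sigma2) == 1L, sigma2 >= 0)
  if (sigma2 == 0) return(stats::plogis(eta))
  r <- gh_rule(nodes)
  out <- numeric(length(eta))
  s <- sqrt(sigma2)
  for (k in seq_along(r$z)) out <- out + r$w[k] * stats::plogis(eta + s * r$z[k])
  out
}

# Deterministic per-stage seed fan-out: each pipeline stage consumes a seed
# derived from the master seed and a fixed stage code, so adding or reordering
# requested methods never perturbs another stage's random stream.
stage_codes <- c(
  simulate = 1L, mc_truth = 2L, bootstrap = 3L, bayes = 4L, evaluate = 5L
)

derive_seed <- function(master_seed, stage) {
  stopifnot(stage %in% names(stage_codes))
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit integers
  as.integer((as.double(master_seed) %% m * 48271 + stage_codes[[stage]] * 7919) %% m)
}

# Half-away-from-zero rounding, matching conventional table formatting
# (base round() rounds half to even).
round_half_away <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
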