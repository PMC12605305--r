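#' Covariate schema for synthetic cohorts
#'
#' A schema declares the patient-level covariates of the outcome model: each
#' variable has a name, an ordered set of levels (the first level is the
#' reference under treatment contrasts) and marginal sampling probabilities.
#' Covariates are drawn independently across variables unless a joint sampler
#' is supplied to [generate_cohort()].
#'
#' @param variables a list; each element is a list with fields `name`
#'   (character), `levels` (character, length `>= 2`) and optionally `probs`
#'   (numeric, same length as `levels`, summing to 1; uniform if omitted).
#' @return an object of class `covariate_schema`.
#' @seealso [default_schema()] for the registry-style default.
#' @export
covariate_schema <- function(variables) {
  stopifnot(is.list(variables), length(variables) >= 1L)
  vars <- lapply(variables, function(v) {
    if (is.null(v$name) || !is.character(v$name) || length(v$name) != 1L)
      stop("each schema variable needs a single character `name`", call. = FALSE)
    if (is.null(v$levels) || length(v$levels) < 2L)
      stop(sprintf("variable '%s' must have >= 2 levels", v$name), call. = FALSE)
    lv <- as.character(v$levels)
    if (anyDuplicated(lv))
      stop(sprintf("variable '%s' has duplicated levels", v$name), call. = FALSE)
    pr <- v$probs %||% rep(1 / length(lv), length(lv))
    if (length(pr) != length(lv) || any(pr < 0))
      stop(sprintf("variable '%s': probs must be nonnegative, one per level", v$name),
           call. = FALSE)
    if (abs(sum(pr) - 1) > 1e-12)
      stop(sprintf("variable '%s': level probabilities must sum to 1", v$name),
           call. = FALSE)
    list(name = v$name, levels = lv, probs = as.numeric(pr))
  })
  nm <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("schema variable names must be unique", call. = FALSE)
  names(vars) <- nm
  structure(list(variables = vars), class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema:", length(x$variables), "variables\n")
  for (v in x$variables) {
    cat(sprintf("  %-12s %d levels: %s\n", v$name, length(v$levels),
                paste(v$levels, collapse = ", ")))
  }
  invisible(x)
}

schema_names <- function(schema) {
  vapply(schema$variables, `[[`, character(1), "name")
}

#' Default covariate schema
#'
#' The default patient-mix schema for dialysis-center cohorts: gender (2),
#' age group (7 bands from 16-25 to 76+), Indigenous status (2), lung disease
#' (2), diabetes (2), cardiovascular disease (2), late referral (2), obesity
#' indicator BMI >= 30 (2), Modified Monash remoteness category (MM1-MM7) and
#' calendar period (2012-2015, 2016-2019, 2020-2023). Marginal level
#' probabilities are uniform by default; pass your own schema to override.
#'
#' @return a `covariate_schema`.
#' @export
default_schema <- function() {
  yn <- c("no", "yes")
  covariate_schema(list(
    list(name = "gender",     levels = c("female", "male")),
    list(name = "agegp",      levels = c("16-25", "26-35", "36-45", "46-55",
                                         "56-65", "66-75", "76+")),
    list(name = "indigenous", levels = yn),
    list(name = "lung",       levels = yn),
    list(name = "diabetes",   levels = yn),
    list(name = "cvd",        levels = yn),
    list(name = "late",       levels = yn),
    list(name = "bmi30",      levels = yn),
    list(name = "mmm",        levels = paste0("MM", 1:7)),
    list(name = "timegp",     levels = c("2012-2015", "2016-2019", "2020-2023"))
  ))
}

# Small schema used for fast simulation studies; same structure, fewer cells.
#' Reduced covariate schema
#'
#' Three binary covariates with uniform marginals. Used for simulation suites
#' where the covariate mix is not the object of study and fit speed matters.
#'
#' @return a `covariate_schema`.
#' @export
reduced_schema <- function() {
  yn <- c("no", "yes")
  covariate_schema(list(
    list(name = "indigenous", levels = yn),
    list(name = "diabetes",   levels = yn),
    list(name = "late",       levels = yn)
  ))
}

#' Simulation configuration
#'
#' Fully determines a synthetic cohort: center count and sizes, the true
#' coefficient vector on the design-matrix scale (intercept first, then one
#' coefficient per non-reference level of each schema variable, in schema
#' order), the random-intercept variance, optional per-center additive logit
#' offsets for planting low/high performers, and the seed.
#'
#' @param n_centers positive integer.
#' @param center_sizes integer vector of length `n_centers`, all `>= 1`.
#' @param beta_true numeric coefficient vector incl. intercept.
#' @param sigma_u2_true random-intercept variance, `>= 0`.
#' @param outlier_offsets named numeric vector; names are center indices
#'   (1-based) and values additive shifts on the logit scale. Default none.
#' @param seed integer seed.
#' @param center_labels optional character labels (length `n_centers`).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_centers, center_sizes, beta_true, sigma_u2_true,
                              outlier_offsets = numeric(0), seed = 1L,
                              center_labels = NULL) {
  assert_scalar_number(n_centers, "n_centers", lower = 1)
  if (length(center_sizes) != n_centers)
    stop("`center_sizes` must have length `n_centers`", call. = FALSE)
  if (any(center_sizes < 1) || any(center_sizes != floor(center_sizes)))
    stop("`center_sizes` must be positive integers", call. = FALSE)
  assert_scalar_number(sigma_u2_true, "sigma_u2_true", lower = 0)
  if (length(outlier_offsets)) {
    idx <- suppressWarnings(as.integer(names(outlier_offsets)))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_centers))
      stop("outlier offset names must be center indices in 1..n_centers",
           call. = FALSE)
  }
  labels <- center_labels %||% make_center_labels(n_centers)
  if (length(labels) != n_centers || anyDuplicated(labels))
    stop("`center_labels` must be unique and of length `n_centers`", call. = FALSE)
  structure(list(
    n_centers = as.integer(n_centers),
    center_sizes = as.integer(center_sizes),
    beta_true = as.numeric(beta_true),
    sigma_u2_true = as.numeric(sigma_u2_true),
    outlier_offsets = outlier_offsets,
    seed = as.integer(seed),
    center_labels = labels
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d centers, %d patients, sigma_u2 = %g, seed = %d\n",
              x$n_centers, sum(x$center_sizes), x$sigma_u2_true, x$seed))
  if (length(x$outlier_offsets))
    cat("  planted offsets at centers:",
        paste(x$center_labels[as.integer(names(x$outlier_offsets))],
              collapse = ", "), "\n")
  invisible(x)
}

# 36 centers are labelled AI, AN, BI, BN, ..., RI, RN (18 letters x
# Indigenous/non-Indigenous suffix); other counts get C01, C02, ...
make_center_labels <- function(n) {
  if (n == 36L) {
    as.vector(t(outer(LETTERS[1:18], c("I", "N"), paste0)))
  } else {
    sprintf("C%02d", seq_len(n))
  }
}

#' Default true coefficients for a schema
#'
#' A plausible coefficient vector on the design-matrix scale (treatment
#' contrasts, first level reference): modest negative effects for comorbidity
#' and access covariates, a mild downward age trend, and a small upward period
#' trend. Values are conventions of the generator, chosen to give a pooled
#' outcome prevalence near 0.45 under uniform marginals.
#'
#' @param schema a `covariate_schema`.
#' @param intercept intercept on the logit scale (default 0.5).
#' @return named numeric vector, intercept first.
#' @export
default_beta <- function(schema = default_schema(), intercept = 0.5) {
  per_var <- list(
    gender = -0.10, agegp = -0.05, indigenous = -0.35, lung = -0.10,
    diabetes = -0.15, cvd = -0.12, late = -0.25, bmi30 = -0.08,
    mmm = -0.04, timegp = 0.08
  )
  beta <- c("(Intercept)" = intercept)
  for (v in schema$variables) {
    L <- length(v$levels)
    slope <- per_var[[v$name]] %||% -0.10
    b <- slope * seq_len(L - 1L)
    names(b) <- paste0(v$name, v$levels[-1L])
    beta <- c(beta, b)
  }
  beta
}

#' Default simulation configuration
#'
#' Mirrors the footprint of a national registry extract: 36 centers labelled
#' AI..RN, heterogeneous sizes summing to 10,195 patients, random-intercept
#' variance 0.04 and the [default_beta()] coefficients for [default_schema()].
#' Center sizes follow a fixed log-normal quantile profile (deterministic),
#' so small rural units and large metropolitan units coexist.
#'
#' @param seed integer seed.
#' @param sigma_u2_true random-intercept variance (default 0.04).
#' @param schema schema the coefficients are built for.
#' @param outlier_offsets optional planted logit offsets, see
#'   [simulation_config()].
#' @return a `simulation_config`.
#' @export
default_config <- function(seed = 1L, sigma_u2_true = 0.04,
                           schema = default_schema(),
                           outlier_offsets = numeric(0)) {
  sizes <- registry_center_sizes(36L, 10195L)
  simulation_config(
    n_centers = 36L, center_sizes = sizes,
    beta_true = default_beta(schema),
    sigma_u2_true = sigma_u2_true,
    outlier_offsets = outlier_offsets, seed = seed
  )
}

# Deterministic heterogeneous size profile: log-normal quantiles rescaled to
# the target total, floored at 30 patients per center.
registry_center_sizes <- function(n, total) {
  q <- stats::qlnorm(stats::ppoints(n), meanlog = 0, sdlog = 0.8)
  sizes <- pmax(30L, as.integer(round(q / sum(q) * total)))
  # fix rounding drift on the largest center
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (total - sum(sizes))
  sizes
}
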