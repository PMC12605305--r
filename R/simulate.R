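#' Generate a synthetic cohort with known truth
#'
#' Draws a patient-level cohort under the random-intercept logistic model:
#' covariates independently from the schema marginals, center effects
#' `u_c ~ N(0, sigma_u2_true)` plus any planted offset, and outcomes
#' `y_ci ~ Bernoulli(plogis(x'beta + u_c + offset_c))`. Identical
#' (config, schema) pairs give byte-identical output.
#'
#' @param config a [simulation_config()].
#' @param schema a [covariate_schema()]; its design matrix (treatment
#'   contrasts) must match `config$beta_true` in length.
#' @param joint_sampler optional function `(n) -> data.frame` of covariate
#'   columns, replacing the independent marginal draws (levels must still be
#'   declared in the schema).
#' @return a list with components `cohort` (data.frame: `center_id`, `y`,
#'   covariates as character columns) and `truth` (class `truth_bundle`:
#'   `beta_true`, `sigma_u2_true`, `u_true` incl. offsets, `p_true`,
#'   `eta_true`, design matrix `X`, center index, and marginal expected
#'   counts `E_marginal` per center).
#' @export
generate_cohort <- function(config, schema = default_schema(),
                            joint_sampler = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(schema, "covariate_schema"))
  n <- sum(config$center_sizes)
  set.seed(config$seed)

  if (is.null(joint_sampler)) {
    covs <- lapply(schema$variables, function(v) {
      sample(v$levels, n, replace = TRUE, prob = v$probs)
    })
    covs <- as.data.frame(covs, stringsAsFactors = FALSE)
  } else {
    covs <- as.data.frame(joint_sampler(n), stringsAsFactors = FALSE)
    check_levels(covs, schema)
  }
  names(covs) <- schema_names(schema)

  center_idx <- rep.int(seq_len(config$n_centers), config$center_sizes)
  center_id <- config$center_labels[center_idx]

  X <- schema_design(covs, schema)
  if (ncol(X) != length(config$beta_true)) {
    stop(sprintf(
      "dimension mismatch: design matrix has %d columns but beta_true has %d",
      ncol(X), length(config$beta_true)), call. = FALSE)
  }

  u <- stats::rnorm(config$n_centers, 0, sqrt(config$sigma_u2_true))
  offsets <- numeric(config$n_centers)
  if (length(config$outlier_offsets))
    offsets[as.integer(names(config$outlier_offsets))] <- config$outlier_offsets
  u_true <- u + offsets

  eta_fix <- drop(X %*% config$beta_true)
  eta <- eta_fix + u_true[center_idx]
  p_true <- stats::plogis(eta)
  y <- stats::rbinom(n, 1L, p_true)

  cohort <- data.frame(center_id = center_id, y = as.integer(y), covs,
                       stringsAsFactors = FALSE)

  p_marg <- marginal_invlogit(eta_fix, config$sigma_u2_true)
  E_marg <- as.numeric(rowsum(p_marg, center_idx))

  truth <- structure(list(
    beta_true = config$beta_true,
    sigma_u2_true = config$sigma_u2_true,
    u_true = stats::setNames(u_true, config$center_labels),
    offsets = stats::setNames(offsets, config$center_labels),
    p_true = p_true,
    eta_true = eta,
    eta_fixed = eta_fix,
    X = X,
    center_idx = center_idx,
    center_labels = config$center_labels,
    E_marginal = stats::setNames(E_marg, config$center_labels),
    mc_true_var = NULL,
    mc_reps = NA_integer_
  ), class = "truth_bundle")

  list(cohort = cohort, truth = truth)
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat(sprintf("Truth bundle: %d centers, %d patients, sigma_u2 = %g\n",
              length(x$center_labels), length(x$p_true), x$sigma_u2_true))
  if (!is.null(x$mc_true_var))
    cat(sprintf("  Monte Carlo truth attached (%d reps)\n", x$mc_reps))
  invisible(x)
}

# Redraw outcomes only, holding covariates and realized center effects fixed.
# This is the sampling experiment under which the Log-SIR variance of a center
# is defined: the center keeps its own patient mix and its own true effect.
#' Redraw outcomes for a fixed truth bundle
#'
#' @param truth a `truth_bundle` from [generate_cohort()].
#' @return integer 0/1 vector of length `nrow(truth$X)`. Uses the current RNG
#'   state; seed externally.
#' @export
regenerate_outcomes <- function(truth) {
  stopifnot(inherits(truth, "truth_bundle"))
  stats::rbinom(length(truth$p_true), 1L, truth$p_true)
}

# Build the treatment-contrast design matrix with the level order the schema
# declares, independent of which levels happen to occur in the data.
schema_design <- function(covs, schema) {
  fcts <- covs
  for (v in schema$variables) {
    bad <- !(covs[[v$name]] %in% v$levels)
    if (any(bad)) {
      stop(sprintf("variable '%s': undeclared level '%s' at row %d",
                   v$name, covs[[v$name]][which(bad)[1]], which(bad)[1]),
           call. = FALSE)
    }
    fcts[[v$name]] <- factor(covs[[v$name]], levels = v$levels)
  }
  stats::model.matrix(~ ., data = fcts)
}

check_levels <- function(covs, schema) {
  nm <- schema_names(schema)
  if (!all(nm %in% names(covs)))
    stop("joint sampler must return every schema variable", call. = FALSE)
  invisible(schema_design(covs[nm], schema))
}

#' Monte Carlo ground-truth variance of Log-SIR per center
#'
#' The oracle the variance estimators are scored against. The covariate
#' matrix and the realized center effects `u_true` are held fixed at the
#' values in the truth bundle; only outcomes are redrawn `reps` times. Each
#' replicate recomputes `O_c` and `log(O_c / E_c)` with `E_c` fixed at the
#' marginal-model expected count (random intercept integrated out, the same
#' functional the estimators target). Replicates with `O_c = 0` are excluded
#' from a center's variance and counted.
#'
#' @param config a [simulation_config()] (regenerated deterministically), or
#'   pass `truth` directly.
#' @param schema schema used with `config`.
#' @param reps number of Monte Carlo replicates (`>= 100`).
#' @param seed seed for the outcome redraws.
#' @param truth optionally, an existing `truth_bundle` (overrides
#'   `config`/`schema`).
#' @return a data.frame with columns `center_id`, `n`, `E`, `true_var`,
#'   `n_used`, `n_excluded`. Centers where every replicate was degenerate get
#'   `true_var = NA` with a warning.
#' @export
monte_carlo_true_variance <- function(config = NULL, schema = default_schema(),
                                      reps = 1000L, seed = 1L, truth = NULL) {
  if (reps < 100L) stop("`reps` must be >= 100", call. = FALSE)
  if (is.null(truth)) {
    stopifnot(inherits(config, "simulation_config"))
    truth <- generate_cohort(config, schema)$truth
  }
  C <- length(truth$center_labels)
  E <- truth$E_marginal
  set.seed(seed)

  draws <- matrix(NA_real_, nrow = reps, ncol = C)
  for (r in seq_len(reps)) {
    y <- stats::rbinom(length(truth$p_true), 1L, truth$p_true)
    O <- as.numeric(rowsum(y, truth$center_idx))
    ok <- O > 0
    draws[r, ok] <- log(O[ok] / E[ok])
  }
  n_used <- colSums(!is.na(draws))
  n_excl <- reps - n_used
  true_var <- rep(NA_real_, C)
  for (c in seq_len(C)) {
    if (n_used[c] >= 2L) true_var[c] <- stats::var(draws[, c], na.rm = TRUE)
  }
  if (any(n_used == 0L)) {
    warning(sprintf(
      "no defined Log-SIR replicate for center(s) %s; truth flagged missing",
      paste(truth$center_labels[n_used == 0L], collapse = ", ")))
  }
  data.frame(
    center_id = truth$center_labels,
    n = as.integer(tabulate(truth$center_idx, C)),
    E = as.numeric(E),
    true_var = true_var,
    n_used = as.integer(n_used),
    n_excluded = as.integer(n_excl),
    stringsAsFactors = FALSE
  )
}

#' Write / read a cohort CSV
#'
#' Fixed-header UTF-8 CSV with columns `center_id,y,<covariates>`. The
#' round-trip is lossless: all covariates are stored as character levels.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(c("center_id", "y") %in% names(cohort)))
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param schema optional schema; if given, covariate columns and levels are
#'   validated against it and parse errors name the offending row.
#' @return `read_cohort()` returns the cohort data.frame.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                       fileEncoding = "UTF-8")
  if (!"center_id" %in% names(d))
    stop("cohort file is missing the `center_id` column", call. = FALSE)
  if (!"y" %in% names(d))
    stop("cohort file is missing the `y` column", call. = FALSE)
  bad_y <- !(d$y %in% c("0", "1"))
  if (any(bad_y))
    stop(sprintf("non-binary outcome value '%s' at row %d",
                 d$y[which(bad_y)[1]], which(bad_y)[1]), call. = FALSE)
  d$y <- as.integer(d$y)
  if (!is.null(schema)) {
    nm <- schema_names(schema)
    extra <- setdiff(names(d), c("center_id", "y", nm))
    if (length(extra))
      stop(sprintf("unknown column(s): %s", paste(extra, collapse = ", ")),
           call. = FALSE)
    missing_cols <- setdiff(nm, names(d))
    if (length(missing_cols))
      stop(sprintf("missing covariate column(s): %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    for (v in schema$variables) {
      bad <- !(d[[v$name]] %in% v$levels)
      if (any(bad))
        stop(sprintf("variable '%s': unknown level '%s' at row %d",
                     v$name, d[[v$name]][which(bad)[1]], which(bad)[1]),
             call. = FALSE)
    }
    d <- d[, c("center_id", "y", nm)]
  }
  d
}
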