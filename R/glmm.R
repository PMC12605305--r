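#' Model specification for the random-intercept logistic fit
#'
#' @param outcome name of the 0/1 outcome column (default `"y"`).
#' @param fixed character vector of fixed-effect covariate columns, expanded
#'   with treatment contrasts (first observed-or-declared level is the
#'   reference).
#' @param group grouping column identifying centers (default `"center_id"`).
#' @param schema optional [covariate_schema()]; when given, factor levels and
#'   reference categories follow the schema declaration rather than the data.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome = "y", fixed, group = "center_id",
                       schema = NULL) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(group), length(group) == 1L)
  if (missing(fixed)) {
    fixed <- if (is.null(schema)) character(0) else schema_names(schema)
  }
  structure(list(outcome = outcome, fixed = as.character(fixed),
                 group = group, schema = schema),
            class = "model_spec")
}

spec_from_schema <- function(schema) model_spec(fixed = schema_names(schema),
                                                schema = schema)

fixed_rhs <- function(spec) {
  if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
}

# Coerce covariate columns to factors with a stable level order.
spec_factors <- function(cohort, spec) {
  d <- cohort
  for (v in spec$fixed) {
    if (!v %in% names(d))
      stop(sprintf("fixed-effect column '%s' not found in cohort", v),
           call. = FALSE)
    lev <- if (!is.null(spec$schema) && v %in% names(spec$schema$variables)) {
      spec$schema$variables[[v]]$levels
    } else {
      sort(unique(as.character(d[[v]])))
    }
    bad <- !(as.character(d[[v]]) %in% lev)
    if (any(bad))
      stop(sprintf("variable '%s': unseen level '%s'", v,
                   as.character(d[[v]])[which(bad)[1]]), call. = FALSE)
    d[[v]] <- factor(as.character(d[[v]]), levels = lev)
  }
  d
}

#' Fit the random-intercept logistic regression
#'
#' Maximizes the Laplace approximation to the marginal likelihood of
#' `logit(p_ci) = x'beta + u_c`, `u_c ~ N(0, sigma_u2)`, via
#' [lme4::glmer()], and exposes everything the downstream variance
#' estimators need.
#'
#' @param cohort cohort data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param spec a [model_spec()].
#' @param control optional [lme4::glmerControl()].
#' @return an object of class `glmm_fit` with components `beta_hat`,
#'   `cov_beta`, `sigma_u2_hat`, `u_hat` (conditional modes, named by
#'   center), `eta_hat` (conditional linear predictor per patient), `p_hat`
#'   (`plogis(eta_hat)`), `loglik`, `converged`, plus the fixed-effect design
#'   matrix `X`, center index and labels used.
#' @export
fit_glmm <- function(cohort, spec, control = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  y <- cohort[[spec$outcome]]
  if (is.null(y)) stop(sprintf("outcome column '%s' not found", spec$outcome),
                       call. = FALSE)
  centers <- unique(as.character(cohort[[spec$group]]))
  if (length(centers) < 2L)
    stop("at least 2 centers are required (sigma_u2 is unidentifiable from one)",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant; the model is not estimable", call. = FALSE)

  d <- spec_factors(cohort, spec)
  d[[spec$group]] <- factor(as.character(d[[spec$group]]), levels = centers)
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(
    spec$outcome, "~", rhs, "+ (1 |", spec$group, ")"))

  control <- control %||% lme4::glmerControl(calc.derivs = FALSE)
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = d, family = stats::binomial(), control = control),
    warning = function(w) {
      if (grepl("converge|Hessian|singular", conditionMessage(w),
                ignore.case = TRUE)) converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  )
  if (!converged)
    warning("glmm fit did not cleanly converge; inspect `converged` flag",
            call. = FALSE)

  beta_hat <- lme4::fixef(fit)
  cov_beta <- as.matrix(stats::vcov(fit))
  sigma_u2_hat <- as.numeric(lme4::VarCorr(fit)[[spec$group]][1, 1])
  re <- lme4::ranef(fit)[[spec$group]]
  u_hat <- stats::setNames(re[, 1], rownames(re))[centers]

  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = d)
  center_idx <- match(as.character(cohort[[spec$group]]), centers)
  eta_hat <- drop(X %*% beta_hat) + u_hat[center_idx]
  p_hat <- stats::plogis(eta_hat)

  structure(list(
    beta_hat = beta_hat,
    cov_beta = cov_beta,
    sigma_u2_hat = sigma_u2_hat,
    u_hat = u_hat,
    eta_hat = as.numeric(eta_hat),
    p_hat = as.numeric(p_hat),
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    X = X,
    center_idx = center_idx,
    center_labels = centers,
    spec = spec,
    model = fit
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic fit: %d patients, %d centers, %d fixed effects\n",
    length(x$p_hat), length(x$center_labels), length(x$beta_hat)))
  cat(sprintf("  sigma_u2_hat = %.5f, logLik = %.2f, converged = %s\n",
              x$sigma_u2_hat, x$loglik, x$converged))
  invisible(x)
}

#' Predicted probabilities from a fitted model
#'
#' `mode = "conditional"` plugs in the center's predicted random intercept:
#' `plogis(x'beta + u_c)`. `mode = "marginal"` integrates the random effect
#' out over `N(0, sigma_u2_hat)` by 41-node Gauss-Hermite quadrature; this is
#' the convention for expected counts under indirect standardization, since a
#' center's own effect must not enter its own expected count.
#'
#' @param fit a `glmm_fit`.
#' @param cohort cohort rows to predict for; defaults to the fitting data
#'   (required for conditional predictions on new centers).
#' @param mode `"marginal"` or `"conditional"`.
#' @param nodes Gauss-Hermite node count (default 41).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_probabilities <- function(fit, cohort = NULL,
                                  mode = c("marginal", "conditional"),
                                  nodes = 41L) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "glmm_fit"))
  if (is.null(cohort)) {
    eta_fix <- drop(fit$X %*% fit$beta_hat)
    center_idx <- fit$center_idx
  } else {
    d <- spec_factors(cohort, fit$spec)
    X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs(fit$spec))),
                             data = d)
    if (!identical(colnames(X), names(fit$beta_hat)))
      stop("cohort design columns do not match the fitted coefficients",
           call. = FALSE)
    eta_fix <- drop(X %*% fit$beta_hat)
    center_idx <- match(as.character(cohort[[fit$spec$group]]),
                        fit$center_labels)
  }
  if (mode == "conditional") {
    if (anyNA(center_idx))
      stop("conditional prediction for a center absent from the fit",
           call. = FALSE)
    stats::plogis(eta_fix + fit$u_hat[center_idx])
  } else {
    marginal_invlogit(eta_fix, fit$sigma_u2_hat, nodes = nodes)
  }
}

#' Export a fit summary as JSON
#'
#' @param fit a `glmm_fit`.
#' @param path output path.
#' @export
write_fit_summary <- function(fit, path) {
  se <- sqrt(diag(fit$cov_beta))
  jsonlite::write_json(list(
    coefficients = as.list(fit$beta_hat),
    se = as.list(stats::setNames(se, names(fit$beta_hat))),
    sigma_u2_hat = fit$sigma_u2_hat,
    loglik = fit$loglik,
    converged = fit$converged,
    n = length(fit$p_hat),
    n_centers = length(fit$center_labels)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
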