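#' Validate and load a run configuration
#'
#' Reads a YAML or JSON configuration describing an end-to-end run and
#' returns either a fully-typed `run_config` with defaults filled in
#' (bootstrap `B = 5000`; MCMC 25,500 iterations, 500 burn-in, 3 chains,
#' thinning 1; `level = 0.95`) or stops with every violation found, not just
#' the first.
#'
#' Recognized top-level keys: `seed`, `level`, `methods` (subset of
#' delta/bootstrap/bayes), `out_dir`, exactly one of `cohort_path` or
#' `simulation` (fields of [simulation_config()]; `schema = "default"` or
#' `"reduced"`), optional `bootstrap` ([bootstrap_config()] fields),
#' `bayes` ([bayes_config()] fields) and `evaluation` (`reps`,
#' `mc_reps` for the simulation-truth study; `reps = 0` disables it).
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return an object of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON", call. = FALSE)

  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  methods <- raw$methods
  if (is.null(methods) || !length(methods)) {
    note("missing or empty key `methods`")
  } else if (!all(methods %in% c("delta", "bootstrap", "bayes"))) {
    note(sprintf("unknown method(s): %s",
                 paste(setdiff(methods, c("delta", "bootstrap", "bayes")),
                       collapse = ", ")))
  }
  level <- raw$level %||% 0.95
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    note("`level` must be a number in (0, 1)")
  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) note("`seed` must be an integer")

  has_cohort <- !is.null(raw$cohort_path)
  has_sim <- !is.null(raw$simulation)
  if (has_cohort == has_sim)
    note("exactly one of `cohort_path` or `simulation` must be present")

  sim_cfg <- NULL
  schema <- default_schema()
  if (has_sim && !has_cohort) {
    s <- raw$simulation
    schema <- switch(s$schema %||% "default",
                     default = default_schema(),
                     reduced = reduced_schema(),
                     { note(sprintf("unknown schema '%s'", s$schema)); NULL })
    if (!is.null(schema)) {
      sim_cfg <- tryCatch({
        if (is.null(s$n_centers) && is.null(s$center_sizes)) {
          default_config(seed = as.integer(seed),
                         sigma_u2_true = s$sigma_u2_true %||% 0.04,
                         schema = schema)
        } else {
          offs <- unlist(s$outlier_offsets %||% list())
          simulation_config(
            n_centers = s$n_centers,
            center_sizes = s$center_sizes,
            beta_true = s$beta_true %||% default_beta(schema),
            sigma_u2_true = s$sigma_u2_true %||% 0.04,
            outlier_offsets = offs,
            seed = as.integer(s$seed %||% seed))
        }
      }, error = function(e) { note(conditionMessage(e)); NULL })
    }
  }

  boot <- tryCatch(do.call(bootstrap_config, c(
    raw$bootstrap %||% list(),
    list(seed = as.integer(derive_seed(seed, "bootstrap")), level = level))),
    error = function(e) { note(paste("bootstrap:", conditionMessage(e))); NULL })
  bayes <- tryCatch(do.call(bayes_config, c(
    raw$bayes %||% list(),
    list(seed = as.integer(derive_seed(seed, "bayes"))))),
    error = function(e) { note(paste("bayes:", conditionMessage(e))); NULL })

  eval_cfg <- raw$evaluation %||% list(reps = 0L)
  eval_cfg$reps <- as.integer(eval_cfg$reps %||% 0L)
  eval_cfg$mc_reps <- as.integer(eval_cfg$mc_reps %||% 1000L)

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  structure(list(
    methods = as.character(methods), level = level, seed = as.integer(seed),
    cohort_path = raw$cohort_path, simulation = sim_cfg, schema = schema,
    bootstrap = boot, bayes = bayes, evaluation = eval_cfg,
    out_dir = raw$out_dir %||% "sirvar-output"
  ), class = "run_config")
}

#' Run the full provider-profiling pipeline
#'
#' Orchestrates simulate (or load) -> fit -> center summaries -> the
#' requested variance methods -> comparison tables -> funnel figures ->
#' (optionally) the simulation-truth evaluation, writing every stage output
#' under `out_dir` and returning a run manifest. Stage seeds are derived
#' from the master seed per stage, so adding or reordering methods never
#' changes another method's numbers. On stage failure the completed outputs
#' remain on disk next to an error manifest naming the stage.
#'
#' @param config a `run_config` from [validate_config()], or a path to a
#'   configuration file.
#' @param out_dir overrides the configured output directory.
#' @return the manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sirvar")),
    config = list(methods = config$methods, level = config$level,
                  seed = config$seed),
    seeds = list(), timings = list(), warnings = character(0),
    outputs = character(0)
  )
  add_warning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = add_warning)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[sirvar] stage %-10s %8.2fs", name,
                    manifest$timings[[name]]))
    res
  }
  note_output <- function(p) manifest$outputs <<- c(manifest$outputs, p)
  fail <- function(stage, e) {
    manifest$error <- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # --- data ---------------------------------------------------------------
  truth <- NULL
  tryCatch({
    if (!is.null(config$simulation)) {
      manifest$seeds$simulate <- config$simulation$seed
      gen <- run_stage("simulate", generate_cohort(config$simulation, config$schema))
      cohort <- gen$cohort
      truth <- gen$truth
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      note_output("cohort.csv")
      jsonlite::write_json(list(
        beta_true = truth$beta_true, sigma_u2_true = truth$sigma_u2_true,
        u_true = as.list(truth$u_true), E_marginal = as.list(truth$E_marginal)
      ), file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      note_output("truth.json")
    } else {
      cohort <- run_stage("load", read_cohort(config$cohort_path))
    }
  }, error = function(e) fail("data", e))

  spec <- model_spec(fixed = setdiff(names(cohort), c("center_id", "y")),
                     schema = if (!is.null(config$simulation)) config$schema)

  fit <- tryCatch(run_stage("fit", fit_glmm(cohort, spec)),
                  error = function(e) fail("fit", e))
  write_fit_summary(fit, file.path(out_dir, "fit.json")); note_output("fit.json")

  summ <- tryCatch({
    p_marg <- predict_probabilities(fit, mode = "marginal")
    run_stage("sir", summarize_centers(cohort, p_marg))
  }, error = function(e) fail("sir", e))
  write_center_summary(summ, file.path(out_dir, "centers.csv"))
  note_output("centers.csv")

  estimates <- list()
  if ("delta" %in% config$methods) {
    estimates$delta <- tryCatch(
      run_stage("delta", delta_variance(fit, cohort, summ, level = config$level)),
      error = function(e) fail("delta", e))
  }
  if ("bootstrap" %in% config$methods) {
    manifest$seeds$bootstrap <- config$bootstrap$seed
    estimates$bootstrap <- tryCatch(
      run_stage("bootstrap",
                bootstrap_var_log_sir(cohort, spec, config$bootstrap, fit = fit)),
      error = function(e) fail("bootstrap", e))
  }
  if ("bayes" %in% config$methods) {
    manifest$seeds$bayes <- config$bayes$seed
    estimates$bayes <- tryCatch(run_stage("bayes", {
      dr <- sample_posterior(cohort, spec, config$bayes)
      posterior_log_sir(dr, level = config$level, force = TRUE)
    }), error = function(e) fail("bayes", e))
  }

  for (nm in names(estimates)) {
    f <- sprintf("var_%s.csv", nm)
    write_variance_estimate(estimates[[nm]], file.path(out_dir, f))
    note_output(f)
  }
  utils::write.csv(center_comparison_table(estimates, "ci", config$level),
                   file.path(out_dir, "table_ci.csv"), row.names = FALSE)
  utils::write.csv(center_comparison_table(estimates, "fdr", config$level),
                   file.path(out_dir, "table_fdr.csv"), row.names = FALSE)
  note_output("table_ci.csv"); note_output("table_fdr.csv")

  cls <- do.call(rbind, lapply(names(estimates), function(nm) {
    pts <- funnel_points(estimates[[nm]], level = config$level)
    f <- sprintf("funnel_%s.svg", nm)
    tryCatch(run_stage(paste0("funnel_", nm),
                       render_funnel(pts, nm, file.path(out_dir, f))),
             error = function(e) fail("funnel", e))
    note_output(f)
    pts[, c("center_id", "method", "status")]
  }))
  utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  note_output("classification.csv")

  if (!is.null(truth) && config$evaluation$reps >= 2L) {
    manifest$seeds$mc_truth <- derive_seed(config$seed, "mc_truth")
    manifest$seeds$evaluate <- derive_seed(config$seed, "evaluate")
    report <- tryCatch(run_stage("evaluate", {
      mc <- monte_carlo_true_variance(truth = truth,
                                      reps = config$evaluation$mc_reps,
                                      seed = manifest$seeds$mc_truth)
      est <- replicate_variance_estimates(
        truth, config$schema, methods = config$methods,
        reps = config$evaluation$reps,
        seed = manifest$seeds$evaluate,
        bootstrap = config$bootstrap, bayes = config$bayes)
      evaluate_methods(est, mc)
    }), error = function(e) fail("evaluate", e))
    write_eval_report(report, file.path(out_dir, "evaluation.csv"))
    note_output("evaluation.csv")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Replicate-level variance estimates for the simulation study
#'
#' Holds the truth bundle's covariates and center effects fixed, redraws
#' outcomes `reps` times and, per replicate, refits the model and computes
#' every requested variance estimate. This is the estimator side of the
#' bias/variance/MSE comparison; the truth side is
#' [monte_carlo_true_variance()] on the same bundle.
#'
#' @param truth a `truth_bundle`.
#' @param schema the schema the bundle was generated under.
#' @param methods subset of `c("delta", "bootstrap", "bayes")`.
#' @param reps number of replicate cohorts (`>= 2`).
#' @param seed seed for the outcome redraws.
#' @param bootstrap,bayes configurations for those methods (the bootstrap
#'   runs in `fixed_model` mode here regardless of its configured mode, so a
#'   replicate study stays tractable).
#' @return long data.frame: `rep`, `method`, `center_id`, `est`.
#' @export
replicate_variance_estimates <- function(truth, schema,
                                         methods = "delta", reps = 50L,
                                         seed = 1L,
                                         bootstrap = bootstrap_config(B = 200L),
                                         bayes = bayes_config(iterations = 1500L)) {
  stopifnot(inherits(truth, "truth_bundle"), reps >= 2L)
  spec <- spec_from_schema(schema)
  out <- vector("list", reps)
  base <- data.frame(center_id = truth$center_labels[truth$center_idx],
                     stringsAsFactors = FALSE)
  cov_cols <- reconstruct_covariates(truth, schema)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, 3L * reps)
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[3L * r - 2L])
    y <- regenerate_outcomes(truth)
    cohort <- data.frame(base["center_id"], y = y, cov_cols,
                         stringsAsFactors = FALSE)
    fit <- tryCatch(suppressWarnings(fit_glmm(cohort, spec)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    p_marg <- predict_probabilities(fit, mode = "marginal")
    summ <- summarize_centers(cohort, p_marg)
    res <- list()
    if ("delta" %in% methods) {
      d <- suppressWarnings(delta_variance(fit, cohort, summ))
      res$delta <- data.frame(rep = r, method = "delta",
                              center_id = d$center_id, est = d$var)
    }
    if ("bootstrap" %in% methods) {
      bc <- bootstrap_config(B = bootstrap$B, seed = rep_seeds[3L * r - 1L],
                             stratified = bootstrap$stratified,
                             mode = "fixed_model", level = bootstrap$level)
      b <- suppressWarnings(bootstrap_var_log_sir(cohort, spec, bc, fit = fit))
      res$bootstrap <- data.frame(rep = r, method = "bootstrap",
                                  center_id = b$center_id, est = b$var)
    }
    if ("bayes" %in% methods) {
      byc <- bayes_config(iterations = bayes$iterations,
                          burn_in = bayes$burn_in, chains = bayes$chains,
                          thin = bayes$thin, seed = rep_seeds[3L * r],
                          prior_beta_mean = bayes$prior_beta_mean,
                          prior_beta_var = bayes$prior_beta_var,
                          prior_tau_shape = bayes$prior_tau_shape,
                          prior_tau_rate = bayes$prior_tau_rate)
      dr <- suppressWarnings(sample_posterior(cohort, spec, byc))
      pb <- suppressWarnings(posterior_log_sir(dr, force = TRUE))
      res$bayes <- data.frame(rep = r, method = "bayes",
                              center_id = pb$center_id, est = pb$var)
    }
    out[[r]] <- do.call(rbind, res)
  }
  do.call(rbind, out)
}

# rebuild the character covariate columns from the stored design matrix
reconstruct_covariates <- function(truth, schema) {
  X <- truth$X
  out <- list()
  for (v in schema$variables) {
    cols <- paste0(v$name, v$levels[-1L])
    sub <- X[, cols, drop = FALSE]
    lev_idx <- 1L + as.integer(sub %*% seq_along(v$levels[-1L]))
    out[[v$name]] <- v$levels[lev_idx]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
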