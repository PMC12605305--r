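# Shared fast fixtures: cohorts are always generated in code at test time.

test_schema <- function() reduced_schema()

test_spec <- function() model_spec(fixed = c("indigenous", "diabetes", "late"),
                                   schema = test_schema())

test_config <- function(n_centers = 6, n_c = 200, sigma_u2 = 0.05, seed = 42,
                        intercept = 0.3, offsets = numeric(0)) {
  simulation_config(n_centers, rep(n_c, n_centers),
                    default_beta(test_schema(), intercept),
                    sigma_u2, outlier_offsets = offsets, seed = seed)
}

test_cohort <- function(...) generate_cohort(test_config(...), test_schema())

quiet_fit <- function(cohort) suppressWarnings(fit_glmm(cohort, test_spec()))
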