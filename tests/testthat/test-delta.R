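test_that("component formulas reproduce hand-evaluated values", {
  expect_equal(var_observed(c(0.5, 0.5), 0), 0.5, tolerance = 1e-12)
  expect_equal(var_observed(c(0.5, 0.5), 0.04), 0.505, tolerance = 1e-12)
  expect_equal(var_expected(c(0.5, 0.5), c(0.04, 0.04), 0.04), 0.01,
               tolerance = 1e-12)
  expect_identical(var_expected(c(0.3, 0.7), c(0, 0), 0), 0)
  expect_equal(cov_obs_exp(c(0.5, 0.5), c(0.04, 0.04), 0.04), 0.025,
               tolerance = 1e-12)
  expect_identical(cov_obs_exp(c(0.3, 0.7), c(0, 0), 0), 0)
  v <- var_log_sir_delta(1, 1, 0.505, 0.01, 0.025)
  expect_equal(v$var, 0.465, tolerance = 1e-12)
  expect_equal(v$se, sqrt(0.465), tolerance = 1e-12)
})

test_that("closed-form pairwise sums equal the O(n^2) double loop", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    p <- runif(n, 0.01, 0.99)
    ve <- runif(n, 0, 0.3)
    s2 <- runif(1, 0, 0.5)
    expect_equal(var_observed(p, s2), loop_var_observed(p, s2),
                 tolerance = 1e-12)
    expect_equal(var_expected(p, ve, s2), loop_var_expected(p, ve, s2),
                 tolerance = 1e-12)
    expect_equal(cov_obs_exp(p, ve, s2), loop_cov_obs_exp(p, ve, s2),
                 tolerance = 1e-12)
    # square-root sensitivity variant against its own loop
    a <- p * (1 - p)
    expect_equal(var_observed(p, s2, pairwise = "sqrt"),
                 loop_sqrt_variant(p, sum(a), s2), tolerance = 1e-12)
  }
})

test_that("every component is nondecreasing in the random-effect variance", {
  set.seed(67)
  p <- runif(9, 0.1, 0.9)
  ve <- runif(9, 0, 0.2)
  grid <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(vapply(grid, function(s) var_observed(p, s),
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(grid, function(s) var_expected(p, ve, s),
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(grid, function(s) cov_obs_exp(p, ve, s),
                              numeric(1))) >= 0))
})

test_that("the first-order variance floors at zero with a warning", {
  expect_warning(v <- var_log_sir_delta(1, 1, 0.1, 0.1, 0.2), "floored")
  expect_identical(v$var, 0)
  # independence limit: no expected-count uncertainty
  p <- runif(6, 0.2, 0.8)
  v2 <- var_log_sir_delta(4, 3.5, sum(p * (1 - p)), 0, 0)
  expect_equal(v2$var, sum(p * (1 - p)) / 16, tolerance = 1e-12)
  expect_error(var_log_sir_delta(0, 3, 1, 0, 0), "undefined")
  expect_error(var_observed(numeric(0), 0.1), "non-empty")
  expect_error(var_expected(c(0.5), c(0.1, 0.1), 0.1), "length")
})

test_that("the fixed-effect sensitivity mode matches an explicit loop", {
  gen <- test_cohort(n_centers = 3, n_c = 40, sigma_u2 = 0.05, seed = 71)
  fit <- quiet_fit(gen$cohort)
  d <- suppressWarnings(delta_variance(fit, gen$cohort,
                                       var_eta_mode = "plus_fixed"))
  p_marg <- predict_probabilities(fit, mode = "marginal")
  s <- summarize_centers(gen$cohort, p_marg)
  s2 <- fit$sigma_u2_hat
  V <- fit$cov_beta
  for (c in 1:3) {
    rows <- which(fit$center_idx == c)
    p <- p_marg[rows]; X <- fit$X[rows, , drop = FALSE]
    a <- p * (1 - p)
    n <- length(p)
    ve <- s2 + rowSums((X %*% V) * X)
    vO <- sum(a); vE <- sum(a^2 * ve); cOE <- sum(a * ve)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xx <- drop(X[i, ] %*% V %*% X[j, ])
      vO <- vO + 2 * a[i] * a[j] * s2
      vE <- vE + 2 * a[i] * a[j] * (s2 + xx)
      cOE <- cOE + 2 * a[i] * a[j] * (s2 + xx)
    }
    ref <- vO / s$O[c]^2 + vE / s$E[c]^2 - 2 * cOE / (s$O[c] * s$E[c])
    expect_equal(d$var[c], max(ref, 0), tolerance = 1e-10)
  }
})

test_that("delta estimates track the Monte Carlo truth across effect sizes", {
  # 12 centers x 250 patients; first-order accuracy holds tightly for small
  # and moderate heterogeneity, and to rough magnitude at sigma_u2 = 0.25
  sch <- test_schema()
  for (s2 in c(0, 0.05, 0.25)) {
    cfg <- simulation_config(12, rep(250, 12), default_beta(sch, 0.3), s2,
                             seed = 300 + round(1000 * s2))
    gen <- generate_cohort(cfg, sch)
    mc <- monte_carlo_true_variance(truth = gen$truth, reps = 4000,
                                    seed = 301 + round(1000 * s2))
    R <- 20
    ests <- matrix(NA_real_, R, 12)
    set.seed(302 + round(1000 * s2))
    covs <- gen$cohort[c("indigenous", "diabetes", "late")]
    for (r in seq_len(R)) {
      cohort <- data.frame(center_id = gen$cohort$center_id,
                           y = regenerate_outcomes(gen$truth), covs)
      fit <- quiet_fit(cohort)
      ests[r, ] <- suppressWarnings(delta_variance(fit, cohort))$var
    }
    ratio <- apply(ests, 2, median) / mc$true_var
    if (s2 <= 0.05) {
      expect_true(all(abs(ratio - 1) <= 0.25),
                  label = sprintf("25%% calibration at sigma_u2=%g", s2))
    } else {
      # first-order accuracy degrades for strongly outlying centers; the
      # assertable content is the rough magnitude and the typical center
      expect_true(all(ratio >= 1 / 3 & ratio <= 3),
                  label = "rough-magnitude calibration at sigma_u2=0.25")
      expect_true(abs(median(ratio) - 1) <= 0.4)
    }
  }
})
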