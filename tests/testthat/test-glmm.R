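test_that("with no center effect the fit collapses to plain logistic regression", {
  gen <- test_cohort(n_centers = 10, n_c = 2000, sigma_u2 = 0, seed = 31)
  fit <- quiet_fit(gen$cohort)
  expect_lte(fit$sigma_u2_hat, 0.01)

  # independent oracle: hand-rolled Newton iterations on the same design
  d <- gen$cohort
  for (v in c("indigenous", "diabetes", "late"))
    d[[v]] <- factor(d[[v]], levels = c("no", "yes"))
  X <- model.matrix(~ indigenous + diabetes + late, d)
  or <- newton_logistic(X, d$y)
  se <- sqrt(diag(or$cov))
  expect_true(all(abs(fit$beta_hat - or$beta) < 3 * se))
})

test_that("intercept-only fit recovers a balanced pooled mean", {
  sch <- test_schema()
  gen <- generate_cohort(simulation_config(8, rep(400, 8),
                                           rep(0, length(default_beta(sch))),
                                           0, seed = 17), sch)
  spec <- model_spec(fixed = character(0))
  fit <- suppressWarnings(fit_glmm(gen$cohort, spec))
  se0 <- sqrt(fit$cov_beta[1, 1])
  expect_lt(abs(fit$beta_hat[[1]]), 3 * se0)
  expect_equal(logit(fit$p_hat), fit$eta_hat, tolerance = 1e-10)
})

test_that("random-effect predictions never overshoot the raw center effect", {
  gen <- test_cohort(n_centers = 8, n_c = 150, sigma_u2 = 0.1, seed = 23)
  fit <- suppressWarnings(fit_glmm(gen$cohort, model_spec(fixed = character(0))))
  raw <- tapply(gen$cohort$y, gen$cohort$center_id, mean)[fit$center_labels]
  raw_effect <- logit(raw) - fit$beta_hat[[1]]
  expect_true(all(abs(fit$u_hat) <= abs(raw_effect) + 1e-8))
  expect_true(all(sign(fit$u_hat) == sign(raw_effect)))
})

test_that("relabelling centers permutes u_hat and leaves the rest unchanged", {
  gen <- test_cohort(n_centers = 6, n_c = 150, sigma_u2 = 0.05, seed = 29)
  fit1 <- quiet_fit(gen$cohort)
  relab <- gen$cohort
  map <- setNames(sprintf("Z%02d", 6:1), unique(gen$cohort$center_id))
  relab$center_id <- unname(map[relab$center_id])
  fit2 <- quiet_fit(relab)
  expect_equal(fit1$beta_hat, fit2$beta_hat, tolerance = 1e-8)
  expect_equal(fit1$sigma_u2_hat, fit2$sigma_u2_hat, tolerance = 1e-8)
  expect_equal(unname(fit2$u_hat[map[names(fit1$u_hat)]]),
               unname(fit1$u_hat), tolerance = 1e-8)
})

test_that("Wald intervals cover the true coefficients at near-nominal rate", {
  covered <- matrix(0L, 100, 4)
  sch <- test_schema()
  beta <- default_beta(sch, 0.3)
  for (s in 1:100) {
    gen <- generate_cohort(simulation_config(36, rep(300, 36), beta, 0.25,
                                             seed = 4000 + s), sch)
    fit <- quiet_fit(gen$cohort)
    se <- sqrt(diag(fit$cov_beta))
    covered[s, ] <- abs(fit$beta_hat - beta) <= 1.959964 * se
  }
  expect_true(all(colSums(covered) >= 90))
})

test_that("marginal prediction matches quadrature-free oracles", {
  # degenerate mixing: marginal == conditional == plogis
  expect_identical(marginal_invlogit(c(-1, 0, 2), 0), plogis(c(-1, 0, 2)))
  # symmetry about zero
  expect_equal(marginal_invlogit(0, 1), 0.5, tolerance = 1e-12)
  # 41-node quadrature vs 200,000-point trapezoid
  expect_equal(marginal_invlogit(1, 0.5), trapz_marginal(1, 0.5),
               tolerance = 1e-6)
  # strict monotonicity in the linear predictor
  eta <- seq(-4, 4, by = 0.1)
  expect_true(all(diff(marginal_invlogit(eta, 0.3)) > 0))
})

test_that("prediction modes are consistent with the fitted components", {
  gen <- test_cohort(n_centers = 5, n_c = 200, sigma_u2 = 0.05, seed = 37)
  fit <- quiet_fit(gen$cohort)
  pc <- predict_probabilities(fit, gen$cohort, mode = "conditional")
  expect_equal(unname(pc), fit$p_hat, tolerance = 1e-12)
  pm <- predict_probabilities(fit, gen$cohort, mode = "marginal")
  expect_true(all(pm > 0 & pm < 1))
  # a fit with the boundary estimate propagates exactly
  fit0 <- fit
  fit0$sigma_u2_hat <- 0
  pm0 <- predict_probabilities(fit0, mode = "marginal")
  expect_identical(pm0, plogis(drop(fit0$X %*% fit0$beta_hat)))
})

test_that("degenerate inputs raise explicit errors", {
  gen <- test_cohort(n_centers = 4, n_c = 50, seed = 41)
  one <- gen$cohort[gen$cohort$center_id == gen$cohort$center_id[1], ]
  expect_error(fit_glmm(one, test_spec()), "2 centers")
  flat <- gen$cohort
  flat$y <- 0L
  expect_error(fit_glmm(flat, test_spec()), "constant")
  fit <- quiet_fit(gen$cohort)
  new <- gen$cohort[1:5, ]
  new$diabetes[2] <- "unknown"
  expect_error(predict_probabilities(fit, new), "unknown")
})
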