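test_that("schema and config validation reject malformed inputs", {
  expect_error(covariate_schema(list(list(name = "a", levels = "x"))),
               ">= 2 levels")
  expect_error(covariate_schema(list(
    list(name = "a", levels = c("x", "y"), probs = c(0.6, 0.6)))),
    "sum to 1")
  expect_error(covariate_schema(list(
    list(name = "a", levels = c("x", "y")),
    list(name = "a", levels = c("p", "q")))), "unique")
  expect_error(simulation_config(3, c(10, 10), c(0), 0.1), "length")
  expect_error(simulation_config(2, c(10, 10), c(0), -0.1), "sigma_u2")
  expect_error(simulation_config(2, c(10, 10), c(0), 0.1,
                                 outlier_offsets = c("5" = -1)),
               "1..n_centers")
})

test_that("default configuration matches the registry footprint", {
  cfg <- default_config()
  expect_equal(cfg$n_centers, 36L)
  expect_equal(sum(cfg$center_sizes), 10195L)
  expect_equal(cfg$center_labels[1:4], c("AI", "AN", "BI", "BN"))
  expect_equal(cfg$center_labels[35:36], c("RI", "RN"))
  expect_gt(max(cfg$center_sizes) / min(cfg$center_sizes), 3)  # heterogeneous
  X_cols <- 1L + sum(vapply(default_schema()$variables,
                            function(v) length(v$levels) - 1L, integer(1)))
  expect_length(cfg$beta_true, X_cols)
})

test_that("generation is deterministic and honors the outcome model limits", {
  g1 <- test_cohort(seed = 11)
  g2 <- test_cohort(seed = 11)
  expect_identical(g1, g2)

  # flat model: every true probability is exactly 1/2
  sch <- test_schema()
  beta0 <- rep(0, length(default_beta(sch)))
  flat <- generate_cohort(simulation_config(4, rep(50, 4), beta0, 0, seed = 2), sch)
  expect_true(all(flat$truth$p_true == 0.5))

  # saturated negative intercept: no events
  sat <- generate_cohort(simulation_config(4, rep(50, 4),
                                           c(-20, beta0[-1]), 0, seed = 2), sch)
  expect_true(all(sat$cohort$y == 0))

  # dimension mismatch named explicitly
  expect_error(generate_cohort(simulation_config(2, c(5, 5), c(0, 0), 0.1), sch),
               "dimension mismatch")
})

test_that("pooled prevalence matches the analytic mean over schema marginals", {
  sch <- test_schema()
  beta <- default_beta(sch, 0.3)
  cfg <- simulation_config(36, sirvar:::registry_center_sizes(36L, 10195L),
                           beta, 0.04, seed = 1)
  gen <- generate_cohort(cfg, sch)

  # exact expectation over the 8-cell covariate product distribution,
  # random intercept integrated out by quadrature
  cells <- expand.grid(indigenous = c("no", "yes"), diabetes = c("no", "yes"),
                       late = c("no", "yes"), stringsAsFactors = FALSE)
  Xc <- sirvar:::schema_design(cells, sch)
  eta <- drop(Xc %*% beta)
  pbar <- marginal_invlogit(eta, 0.04)
  analytic_mean <- mean(pbar)

  # approximate SD of the pooled prevalence: within-patient Bernoulli
  # variation plus the between-center random-effect contribution
  a <- mean(pbar * (1 - pbar))
  N <- sum(cfg$center_sizes)
  v <- (N * a + sum(cfg$center_sizes^2) * a^2 * 0.04) / N^2
  expect_lt(abs(mean(gen$cohort$y) - analytic_mean), 3 * sqrt(v))
})

test_that("realized center effects have the declared variance", {
  us <- unlist(lapply(1:30, function(s) {
    generate_cohort(simulation_config(36, rep(5, 36),
                                      default_beta(test_schema()), 0.09,
                                      seed = 500 + s),
                    test_schema())$truth$u_true
  }))
  n <- length(us)
  se <- 0.09 * sqrt(2 / (n - 1))
  expect_lt(abs(mean(us^2) - 0.09), 4 * se)
})

test_that("centers are exchangeable under a flat random-effect-free model", {
  # permutation test on the between-center variance of outcome means;
  # rejections at alpha = 0.01 should stay near nominal across seeds
  n_centers <- 10; n_c <- 60
  rejections <- 0
  for (s in 1:100) {
    gen <- generate_cohort(test_config(n_centers, n_c, sigma_u2 = 0,
                                       seed = 7000 + s), test_schema())
    y <- gen$cohort$y
    idx <- rep(seq_len(n_centers), each = n_c)
    stat <- stats::var(as.numeric(rowsum(y, idx)) / n_c)
    set.seed(s)
    perm <- replicate(199, stats::var(as.numeric(rowsum(y, sample(idx))) / n_c))
    if (mean(perm >= stat) <= 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections / 100, 0.02)
})

test_that("Monte Carlo truth agrees with exact enumeration for small centers", {
  sch <- test_schema()
  cfg <- simulation_config(2, c(8L, 60L), default_beta(sch, 0.2), 0.1, seed = 9)
  gen <- generate_cohort(cfg, sch)
  truth <- gen$truth
  mc <- monte_carlo_true_variance(truth = truth, reps = 40000, seed = 10)

  p1 <- truth$p_true[truth$center_idx == 1]
  en <- enum_logsir_moments(p1, truth$E_marginal[1])
  # 4 standard errors of a sample variance, with the exact fourth moment
  pmf <- poisbinom_pmf(p1)
  w <- pmf[-1] / sum(pmf[-1])
  v <- log(seq_along(p1) / truth$E_marginal[1])
  m4 <- sum(w * (v - en$mean)^4)
  se <- sqrt((m4 - en$var^2) / mc$n_used[1])
  expect_lt(abs(mc$true_var[1] - en$var), 4 * se)
  expect_equal(mc$n_excluded[1] / 40000, en$p_zero, tolerance = 0.15)

  # n = 1 at p = 1/2: conditional on O >= 1 the Log-SIR is constant
  flat <- generate_cohort(simulation_config(2, c(1L, 40L),
                                            rep(0, length(default_beta(sch))),
                                            0, seed = 4), sch)
  mc1 <- monte_carlo_true_variance(truth = flat$truth, reps = 2000, seed = 5)
  expect_identical(mc1$true_var[1], 0)
})

test_that("two Monte Carlo truths at different seeds agree within error", {
  truth <- test_cohort(n_centers = 5, n_c = 150, sigma_u2 = 0.05,
                       seed = 21)$truth
  a <- monte_carlo_true_variance(truth = truth, reps = 500, seed = 1)
  b <- monte_carlo_true_variance(truth = truth, reps = 500, seed = 2)
  # 4 SE of the difference of two variance estimates (normal-theory scale)
  se <- sqrt(2) * a$true_var * sqrt(2 / (a$n_used - 1))
  expect_true(all(abs(a$true_var - b$true_var) < 4 * se))
})

test_that("degenerate centers are flagged missing, never silently zero", {
  sch <- test_schema()
  beta <- c(-20, default_beta(sch)[-1])
  gen <- generate_cohort(simulation_config(2, c(1L, 30L), beta, 0, seed = 3), sch)
  gen$truth$p_true[gen$truth$center_idx == 2] <- 0.6  # keep center 2 alive
  expect_warning(mc <- monte_carlo_true_variance(truth = gen$truth,
                                                 reps = 200, seed = 1),
                 "flagged missing")
  expect_true(is.na(mc$true_var[1]))
})

test_that("cohort CSV round-trip is lossless and parse errors name the row", {
  gen <- test_cohort(n_centers = 3, n_c = 25, seed = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(gen$cohort, f)
  back <- read_cohort(f, schema = test_schema())
  expect_identical(back, gen$cohort)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, f2)
  expect_identical(readLines(f), readLines(f2))

  bad <- gen$cohort
  names(bad)[2] <- "outcome"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort(f), "`y` column")

  bad <- gen$cohort
  bad$y[7] <- 2L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort(f), "row 7")

  bad <- gen$cohort
  bad$diabetes[3] <- "maybe"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_cohort(f, schema = test_schema()), "row 3")
})
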