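# Logistic exposure-model fitting, distributions, and bootstrap CIs.

test_that("unadjusted binary fit reproduces the closed-form 2x2 log-OR", {
  d <- toy_2x2()
  m <- fit_exposure_model(d, "x", outcome = "y")
  expect_equal(unname(m$betas[2]), log(27 / 7), tolerance = 1e-8)
  expect_identical(unname(m$betas[1]), 0)
  expect_equal(m$n_cases, 100L)
  expect_equal(m$n_controls, 100L)
})

test_that("unadjusted fits equal 2x2 log-ORs over random tables", {
  set.seed(7)
  for (i in 1:20) {
    cells <- sample(5:80, 4, replace = TRUE)  # a1,a0 cases; a1,a0 controls
    d <- data.frame(
      y = rep(c(1L, 0L), c(cells[1] + cells[2], cells[3] + cells[4])),
      x = rep(c(1L, 0L, 1L, 0L), cells)
    )
    m <- fit_exposure_model(d, "x", outcome = "y")
    expect_equal(unname(m$betas[2]),
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
  }
})

test_that("a null exposure fits near zero and a true beta is recovered", {
  set.seed(11)
  n <- 10000
  d0 <- data.frame(y = rbinom(n, 1, 0.5), x = rbinom(n, 1, 0.3))
  m0 <- fit_exposure_model(d0, "x", outcome = "y")
  se0 <- sqrt(m0$vcov[2, 2])
  expect_lt(abs(m0$betas[2]), 3 * se0)

  cfg <- sim_config(betas = 0.5, n = 6e5)
  coh <- simulate_cohort(cfg, seed = 1)
  d <- sample_case_control(coh, 5000, 5000, seed = 1)
  m <- fit_exposure_model(d, "a", confounders = "c", outcome = "y")
  se <- sqrt(m$vcov[2, 2])
  expect_lt(abs(m$betas[2] - 0.5), 3 * se)
})

test_that("fitting errors are informative", {
  d <- toy_2x2()
  d$x[d$y == 1] <- 0  # exposed level absent among cases
  expect_error(fit_exposure_model(d, "x", outcome = "y"),
               "degenerate level.*absent among cases or controls")
  expect_error(fit_exposure_model(toy_2x2(), "nope", outcome = "y"),
               "not found")
  d2 <- toy_2x2()
  d2$y <- d2$y + 1
  expect_error(fit_exposure_model(d2, "x", outcome = "y"), "binary")
})

test_that("rows with missing values are dropped with a message", {
  d <- toy_2x2()
  d$x[1:5] <- NA
  expect_message(m <- fit_exposure_model(d, "x", outcome = "y"),
                 "dropped 5 row")
  expect_equal(m$n_cases, 95L)
})

test_that("select_reference_level finds the trimmed argmin of the curve", {
  fake_model <- function(curve, values) {
    structure(list(exposure_kind = "continuous", raw_curve = curve,
                   exposure_values = values),
              class = "exposure_model")
  }
  vals <- seq(0, 10, length.out = 1001)
  # strictly increasing curve: argmin at the lower trim quantile
  m_up <- fake_model(function(j) 0.3 * j, vals)
  expect_equal(select_reference_level(m_up),
               unname(quantile(vals, 0.01)), tolerance = 1e-9)
  # interior quadratic minimum, recovered to grid resolution
  m_q <- fake_model(function(j) (j - 4.3)^2, vals)
  expect_equal(select_reference_level(m_q), 4.3, tolerance = 0.05)
  # constant curve: tie broken to the smallest value
  m_c <- fake_model(function(j) rep(0, length(j)), vals)
  expect_equal(select_reference_level(m_c),
               unname(quantile(vals, 0.01)), tolerance = 1e-9)
  # wrong-kind refusal
  m_b <- fit_exposure_model(toy_2x2(), "x", outcome = "y")
  expect_error(select_reference_level(m_b), "continuous")
})

test_that("control_case_distributions counts level proportions by outcome", {
  d <- toy_2x2()
  cc <- control_case_distributions(d, "x", outcome = "y")
  expect_equal(cc$control_probs, c(0.9, 0.1))
  expect_equal(cc$case_probs, c(0.7, 0.3))
  expect_false(cc$degenerate)

  d$x[d$y == 0] <- 0
  cc2 <- control_case_distributions(d, "x", outcome = "y")
  expect_true(cc2$degenerate)

  dc <- data.frame(y = rep(c(1, 0), c(40, 60)), x = rnorm(100))
  cc3 <- control_case_distributions(dc, "x", outcome = "y")
  expect_length(cc3$control_values, 60)
  expect_length(cc3$case_values, 40)
})

test_that("paf composes fit and distributions into both PAF flavours", {
  f <- paf(y ~ x, toy_2x2())
  expect_s3_class(f, "paf")
  expect_equal(f$exact_paf, 0.3 * (1 - 7 / 27), tolerance = 1e-8)
  expect_equal(f$approx_paf, 0.1 * log(27 / 7), tolerance = 1e-8)
  expect_equal(f$control_prevalence, 0.1)
  expect_equal(f$or_ave, exp(f$beta_ave), tolerance = 1e-12)
  expect_output(print(f), "approx PAF")

  # summary-only entry path
  fs <- paf_from_summary(0.837, 0.501, "physical inactivity")
  expect_equal(fs$approx_paf, 0.837 * 0.501, tolerance = 1e-12)
  expect_equal(round(100 * fs$approx_paf, 1), 41.9)
  expect_true(is.na(fs$exact_paf))
})

test_that("a null simulated exposure yields PAFs near zero", {
  cfg <- sim_config(betas = 0, confounder = NULL, n = 3e5)
  coh <- simulate_cohort(cfg, seed = 21)
  d <- sample_case_control(coh, 1500, 1500, seed = 21)
  f <- suppressWarnings(paf(y ~ a, d))
  expect_lt(abs(f$exact_paf), 0.05)
  expect_lt(abs(f$approx_paf), 0.05)
})

test_that("binary recoding changes approx PAF only through beta_ave", {
  set.seed(13)
  n <- 4000
  a <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  y <- rbinom(n, 1, plogis(-1 + 0.3 * (a == 1) + 0.6 * (a == 2)))
  d <- data.frame(y = y, a = factor(a))
  f_multi <- paf(y ~ a, d, kind = "multicategory")
  d$ab <- as.integer(a > 0)
  f_bin <- paf(y ~ ab, d)
  expect_equal(f_multi$control_prevalence, f_bin$control_prevalence,
               tolerance = 1e-12)
  expect_equal(f_multi$approx_paf / f_multi$beta_ave,
               f_bin$approx_paf / f_bin$beta_ave, tolerance = 1e-12)
})

test_that("bootstrap intervals are reproducible and nested across levels", {
  cfg <- sim_config(n = 2e5)
  coh <- simulate_cohort(cfg, seed = 3)
  d <- sample_case_control(coh, 1200, 1200, seed = 3)
  f <- paf(y ~ a + c, d)
  b1 <- bootstrap_ci(f, n_reps = 99, level = 0.95, seed = 17)
  b2 <- bootstrap_ci(f, n_reps = 99, level = 0.95, seed = 17)
  expect_identical(b1$exact, b2$exact)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(b1$n_fail, 0L)

  b99 <- bootstrap_ci(f, n_reps = 99, level = 0.99, seed = 17)
  # same seed, same resample stream: wider level contains narrower
  expect_lte(b99$exact[1], b1$exact[1])
  expect_gte(b99$exact[2], b1$exact[2])
  expect_lte(b99$approx[1], b1$approx[1])
  expect_gte(b99$approx[2], b1$approx[2])

  ci <- confint(f, level = 0.95, n_reps = 99, seed = 17)
  expect_equal(unname(ci["exact_paf", ]), b1$exact)
  expect_error(bootstrap_ci(f, n_reps = 1), ">= 2")
  expect_error(bootstrap_ci(paf_from_summary(0.5, 0.3)), "subject-level")
})

test_that("the continuous pipeline recovers the average log-OR", {
  # linear dose-response; truth evaluated at each fit's own anchor
  cfg <- sim_config(kind = "continuous", beta_slope = 0.2, n = 3e5)
  est <- t(vapply(1:6, function(s) {
    coh <- simulate_cohort(cfg, seed = s)
    d <- sample_case_control(coh, 5000, 5000, seed = s + 100)
    f <- paf(y ~ a + c, d)
    truth <- 0.2 * (mean(d$a[d$y == 0]) - f$model$reference_value)
    c(est = f$beta_ave, truth = truth)
  }, c(0, 0)))
  dev <- est[, "est"] - est[, "truth"]
  mc_se <- sd(dev)
  expect_lt(abs(dev[1]), 3 * mc_se)
  # and the estimator is unbiased across replicates
  expect_lt(abs(mean(dev)), 3 * mc_se / sqrt(nrow(est)))
})

test_that("summary tables round-trip through the CSV schema", {
  tab <- paf_table(list(paf(y ~ x, toy_2x2())))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(tab, path)
  back <- read_summary_table(path)
  expect_equal(back$approx_paf, tab$approx_paf, tolerance = 1e-9)
  expect_true(all(c("factor", "kind", "prevalence", "beta_ave", "or_ave",
                    "approx_paf", "exact_paf", "ci_lower", "ci_upper")
                  %in% names(back)))
})
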