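test_that("profiled fit matches the brute-force dense-likelihood oracle", {
  set.seed(30)
  worst_dev <- 0; worst_beta <- 0
  for (i in 1:50) {
    m <- scenario(sample(4, 1), tau = runif(1, 0, 0.5))
    d <- simulate_cohort(m, n = 5)
    fit <- fit_random_intercept_ml(d)
    orc <- oracle_fit(d)
    worst_dev <- max(worst_dev, abs(fit$deviance - orc$deviance))
    worst_beta <- max(worst_beta,
                      abs(fit$fixed_effects["treatment"] -
                            orc$beta["treatment"]))
  }
  expect_lt(worst_dev, 1e-5)
  expect_lt(worst_beta, 1e-4)
})

test_that("profiled fit agrees with an established mixed-model library", {
  skip_if_not_installed("lme4")
  set.seed(31)
  for (i in 1:6) {
    d <- simulate_cohort(scenario((i - 1) %% 4 + 1), n = 8)
    fit <- fit_random_intercept_ml(d)
    ref <- suppressMessages(
      lme4::lmer(outcome ~ treatment + (1 | patient_id),
                 data = as.data.frame(d), REML = FALSE))
    expect_equal(fit$deviance, deviance(ref), tolerance = 1e-6)
    expect_equal(unname(fit$fixed_effects),
                 unname(lme4::fixef(ref)), tolerance = 1e-5)
    expect_lt(max(abs(unname(fit$blups) -
                        lme4::ranef(ref)$patient_id[, 1])), 1e-5)
  }
})

test_that("nesting, BLUP shrinkage and centering hold on random cohorts", {
  set.seed(32)
  for (i in 1:20) {
    d <- simulate_cohort(scenario(sample(4, 1)), n = sample(5:15, 1))
    f1 <- fit_random_intercept_ml(d, include_treatment = TRUE)
    f0 <- fit_random_intercept_ml(d, include_treatment = FALSE)
    expect_gte(f0$deviance - f1$deviance, 0)
    expect_gte(f1$var_patient, 0)
    # BLUPs never exceed the raw patient mean deviation and sum to ~0
    pid <- d$patient_id
    fitted_fix <- f1$fixed_effects[1] + f1$fixed_effects[2] * d$treatment
    raw_dev <- tapply(d$outcome - fitted_fix, pid, mean)
    expect_true(all(abs(f1$blups) <= abs(raw_dev) + 1e-10))
    expect_lt(abs(sum(f1$blups)), 1e-6 * max(1, sum(abs(f1$blups))))
  }
})

test_that("boundary fits collapse to the OLS likelihood", {
  # under homogeneity (sigma_mu = 0) the variance-ratio estimate regularly
  # hits the boundary; there the ML deviance must equal -2 logL of OLS
  set.seed(33)
  hits <- 0
  for (i in 1:20) {
    d <- simulate_cohort(scenario(2), n = 10)
    fit <- fit_random_intercept_ml(d)
    if (fit$var_patient == 0) {
      hits <- hits + 1
      res <- stats::lm(outcome ~ treatment, data = as.data.frame(d))
      n <- nrow(d)
      dev_ols <- n * log(2 * pi * sum(res$residuals^2) / n) + n
      expect_equal(fit$deviance, dev_ols, tolerance = 1e-6)
      expect_true(all(abs(fit$blups) < 1e-8))
    }
  }
  expect_gt(hits, 0)
})

test_that("variance components are consistent in large samples", {
  d <- simulate_cohort(scenario(2, tau = 0.25), n = 2000, seed = 34)
  fit <- fit_random_intercept_ml(d)
  expect_lt(fit$var_patient, 0.01)          # true sigma_mu^2 = 0
  expect_lt(abs(fit$var_error - 0.25), 0.02)
  d3 <- simulate_cohort(scenario(3, tau = 0.25), n = 2000, seed = 35)
  fit3 <- fit_random_intercept_ml(d3)
  expect_lt(abs(fit3$var_patient - 0.25), 0.03)
  expect_lt(abs(fit3$fixed_effects["treatment"] - 0.25), 0.03)
})

test_that("degenerate and invalid inputs are handled explicitly", {
  pat <- make_patient(c(1, 0, 0, 1, 1, 0), tau = 0)
  pat$outcome <- rep(3.5, 6)
  two <- rbind(pat, within(pat, patient_id <- 2L))
  two <- structure(two, design = "nof1",
                   class = c("trial_data", "data.frame"))
  fit <- fit_random_intercept_ml(two)
  expect_equal(unname(fit$fixed_effects["(Intercept)"]), 3.5)
  expect_equal(unname(fit$fixed_effects["treatment"]), 0)
  expect_lte(fit$var_error, 1e-10)          # floored at the lower bound
  # single observation per patient is refused
  co <- simulate_cohort(scenario(1), n = 10, seed = 36)
  rct <- extract_design(co, "rct", seed = 37)
  expect_error(fit_random_intercept_ml(rct), "fit_ols")
  # rank deficiency is an explicit failure
  const <- co
  const$treatment <- 1L
  expect_error(fit_random_intercept_ml(const), "rank")
})

test_that("LRT p-values follow the chi-squared(1) reference", {
  # statistic 0 sits at the survival-function boundary
  pat <- make_patient(c(1, 0, 0, 1, 1, 0), tau = 0)
  pat$outcome <- rep(1, 6)
  two <- structure(rbind(pat, within(pat, patient_id <- 2L)),
                   design = "nof1", class = c("trial_data", "data.frame"))
  res <- lrt_treatment(two)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$rejected)
  # the 0.05 critical value
  expect_equal(stats::pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  # rejected <=> p < alpha, on a real fit
  d <- simulate_cohort(scenario(1, tau = 1), n = 10, seed = 38)
  out <- lrt_treatment(d)
  expect_identical(out$rejected, out$p_value < out$alpha)
  expect_equal(out$method, "lrt_chisq1")
})

test_that("carryover-adjusted LRT keeps one degree of freedom", {
  d <- apply_carryover(simulate_cohort(scenario(1, tau = 0.3), 15,
                                       seed = 39), 0.1)
  f1 <- fit_random_intercept_ml(d, TRUE, include_carryover_covariate = TRUE)
  f0 <- fit_random_intercept_ml(d, FALSE, include_carryover_covariate = TRUE)
  expect_named(f1$fixed_effects,
               c("(Intercept)", "treatment", "prev_treated"))
  expect_named(f0$fixed_effects, c("(Intercept)", "prev_treated"))
  res <- lrt_treatment(d, adjust_carryover = TRUE)
  expect_equal(res$statistic, max(0, f0$deviance - f1$deviance),
               tolerance = 1e-8)
})

test_that("OLS analysis of the parallel arm matches hand computation", {
  d <- structure(
    data.frame(patient_id = 1:6, cycle = 1L, look = 1L,
               treatment = c(0L, 0L, 0L, 1L, 1L, 1L),
               outcome = c(1, 2, 3, 3, 4, 5),
               prev_treated = 0L, population = "representative"),
    design = "rct", class = c("trial_data", "data.frame"))
  res <- fit_ols(d)
  expect_equal(res$estimate, 2)
  expect_equal(res$method, "ols_wald")
  # identical constant arms: zero effect, no rejection
  d$outcome <- rep(2, 6)
  res0 <- fit_ols(d)
  expect_equal(res0$estimate, 0)
  expect_false(res0$rejected)
  # an empty arm is an explicit failure
  d$treatment <- 1L
  expect_error(fit_ols(d), "arm")
})

test_that("fit and test results serialize to JSON records", {
  d <- simulate_cohort(scenario(1), n = 5, seed = 40)
  fit <- fit_random_intercept_ml(d)
  js <- jsonlite::fromJSON(to_json(fit))
  expect_equal(js$deviance, round(fit$deviance, 6))
  expect_equal(js$n_patients, 5)
  res <- jsonlite::fromJSON(to_json(lrt_treatment(d)))
  expect_true(is.logical(res$rejected))
  expect_equal(res$method, "lrt_chisq1")
})
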