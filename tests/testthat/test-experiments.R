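B_PROP <- 400  # property-check replicate count; tolerances scale as 3 mc_se

test_that("operating-characteristic records are internally consistent", {
  oc <- run_oc(scenario(1, tau = 0.25), "nof1", n = 10, B = 150, seed = 50)
  expect_equal(oc$n_reps, 150L)
  # rejection count is an integer and mc_se matches its definition
  k <- oc$rejection_rate * (oc$n_reps - oc$n_excluded)
  expect_lt(abs(k - round(k)), 1e-9)
  expect_lt(abs(oc$mc_se -
                  sqrt(oc$rejection_rate * (1 - oc$rejection_rate) /
                         (oc$n_reps - oc$n_excluded))), 1e-12)
  expect_equal(oc$n_excluded, 0L)
})

test_that("an overwhelming effect is always detected", {
  m <- simulation_model(tau = 5, sigma_mu = 0.5, sigma_eps = 0.5)
  oc <- run_oc(m, "nof1", n = 30, B = 200, seed = 51)
  expect_equal(oc$rejection_rate, 1)
})

test_that("identical root seeds reproduce results bit-for-bit", {
  m <- scenario(2, tau = 0.25)
  a <- run_oc(m, "crossover", n = 20, B = 120, seed = 52)
  b <- run_oc(m, "crossover", n = 20, B = 120, seed = 52)
  expect_identical(a, b)
  g1 <- power_curve(m, "rct", n_grid = c(10, 30), B = 100, seed = 53)
  g2 <- power_curve(m, "rct", n_grid = c(10, 30), B = 100, seed = 53)
  expect_identical(g1, g2)
})

test_that("null calibration holds for all designs and scenarios", {
  for (s in 1:4) {
    m <- scenario(s, tau = 0)
    for (des in c("nof1", "crossover", "rct")) {
      oc <- run_oc(m, des, n = 30, B = B_PROP, seed = 100 + 3 * s +
                     match(des, c("nof1", "crossover", "rct")))
      expect_rate(oc, 0.05)
    }
  }
})

test_that("power ranks N-of-1 above crossover above parallel RCT", {
  for (s in 1:4) {
    m <- scenario(s, tau = 0.25)
    slack <- 0
    rates <- vapply(c("nof1", "crossover", "rct"), function(des) {
      oc <- run_oc(m, des, n = 30, B = B_PROP, seed = 200 + s)
      slack <<- max(slack, 3 * oc$mc_se)
      oc$rejection_rate
    }, numeric(1))
    expect_gte(rates["nof1"], rates["crossover"] - slack)
    expect_gte(rates["crossover"], rates["rct"] - slack)
  }
})

test_that("power is non-decreasing in sample size along the curve", {
  pc <- power_curve(scenario(1, tau = 0.25), "nof1",
                    n_grid = c(10, 20, 50, 150), B = B_PROP, seed = 54)
  slack <- 3 * max(pc$mc_se)
  expect_true(all(diff(pc$rejection_rate) > -slack))
})

test_that("tau_curve at tau = 0 reproduces run_oc with the same seed", {
  m <- scenario(1, tau = 0.25)
  tc <- tau_curve(m, "nof1", tau_grid = c(0, 0.25), n = 15, B = 100,
                  seed = 55)
  m0 <- m; m0$tau <- 0
  oc <- run_oc(m0, "nof1", n = 15, B = 100, seed = tc$seed[1])
  expect_equal(tc$rejection_rate[1], oc$rejection_rate)
})

test_that("minimum-n search returns the smallest qualifying grid point", {
  m <- scenario(1, tau = 0.25)
  # a vanishing target qualifies immediately
  expect_equal(as.integer(min_n_for_power(m, "nof1", target_power = 1e-9,
                                          n_grid = c(10, 20), B = 100,
                                          seed = 56)), 10L)
  # an unreachable target exhausts the grid
  res <- min_n_for_power(scenario(4, tau = 0.05), "rct",
                         target_power = 0.999, n_grid = c(10, 20),
                         B = 100, seed = 57)
  expect_true(is.na(res))
  expect_equal(nrow(attr(res, "curve")), 2L)
  # early stop agrees with the full scan
  full <- min_n_for_power(m, "nof1", 0.8, n_grid = c(10, 20, 30, 40),
                          B = 300, seed = 58, early_stop = FALSE)
  quick <- min_n_for_power(m, "nof1", 0.8, n_grid = c(10, 20, 30, 40),
                           B = 300, seed = 58)
  expect_equal(as.integer(full), as.integer(quick))
  expect_error(min_n_for_power(m, "nof1", 0.8, n_grid = numeric(0)),
               "n_grid")
})

test_that("carryover inflates the unadjusted N-of-1 type-I error", {
  clean <- run_oc(scenario(1, tau = 0), "nof1", n = 40, B = 800, seed = 59)
  infl <- run_oc(scenario(1, tau = 0, carryover = 0.1), "nof1", n = 40,
                 B = 800, seed = 60)
  slack <- 3 * sqrt(clean$mc_se^2 + infl$mc_se^2)
  expect_gt(infl$rejection_rate, clean$rejection_rate + slack)
})

test_that("the carryover-adjusted test restores calibration", {
  adj <- run_oc(scenario(1, tau = 0, carryover = 0.1), "nof1", n = 40,
                B = 800, seed = 61, adjust_carryover = TRUE)
  expect_rate(adj, 0.05)
  # and does not pay for it with power relative to the unadjusted test
  p_adj <- run_oc(scenario(1, tau = 0.25, carryover = 0.1), "nof1", n = 40,
                  B = 800, seed = 62, adjust_carryover = TRUE)
  p_raw <- run_oc(scenario(1, tau = 0.25, carryover = 0.1), "nof1", n = 40,
                  B = 800, seed = 63)
  expect_gte(p_adj$rejection_rate,
             p_raw$rejection_rate -
               3 * sqrt(p_adj$mc_se^2 + p_raw$mc_se^2))
})

test_that("selection-bias driver wires the mixture as documented", {
  m <- scenario(1)
  sb <- selection_bias_oc(m, "nof1", n = 20, p_grid = c(0.5, 1), B = 120,
                          seed = 64, mode = "type1")
  expect_equal(sb$tau, c(0, 0))
  expect_equal(sb$tau_sub, c(0.25, 0.25))
  expect_equal(sb$p_representative, c(0.5, 1))
  pw <- selection_bias_oc(m, "rct", n = 20, p_grid = 0.8, B = 120,
                          seed = 65, mode = "power")
  expect_equal(pw$tau, 0.25)
  expect_equal(pw$tau_sub, 0)
  expect_error(selection_bias_oc(m, "nof1", p_grid = c(0.5, 1.3)), "p_grid")
})

test_that("exchangeable subgroups give centred BLUP differences", {
  # tau_sub = tau: the population label is pure noise
  m <- scenario(1, tau = 0.25, tau_sub = 0.25)
  cmp <- compare_random_effects(m, n = 40, p = 0.5, B = 120, seed = 66)
  for (side in cmp) {
    se <- sd(side$diffs) / sqrt(length(side$diffs))
    expect_lt(abs(mean(side$diffs)), 3 * se + 1e-12)
  }
  expect_error(compare_random_effects(m, n = 40, p = 1, B = 10), "p")
})
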