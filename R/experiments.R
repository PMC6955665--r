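# child seeds: one root seed per experiment, one derived stream per
# replicate (or grid point) so results are reproducible bit-for-bit and
# any single replicate can be re-run in isolation
.child_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

.mc_se <- function(rate, b) sqrt(rate * (1 - rate) / b)

.oc_row <- function(model, design, n, B, seed, rejections, excluded,
                    alpha) {
  b_eff <- B - excluded
  rate <- if (b_eff > 0) rejections / b_eff else NA_real_
  data.frame(design = design, scenario = model$scenario, n = as.integer(n),
             tau = model$tau, gamma = model$carryover,
             p_representative = model$p_representative,
             tau_sub = model$tau_sub, alpha = alpha,
             n_reps = as.integer(B), n_excluded = as.integer(excluded),
             rejection_rate = rate, mc_se = .mc_se(rate, b_eff),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

#' Monte-Carlo operating characteristics of one design at one setting
#'
#' Runs `B` independent replicates of the full pipeline — simulate an
#' N-of-1 cohort from `model`, extract the requested design from the same
#' draws, apply the model's carryover increment under that design's
#' chronology, analyze with the design's standard test — and reports the
#' empirical rejection rate with its Monte-Carlo standard error
#' \eqn{\sqrt{\hat\pi(1-\hat\pi)/B}}. With `tau = 0` (and
#' `p_representative = 1`) the rate estimates the type-I error
#' probability; otherwise it estimates power.
#'
#' Replicates whose analysis fails (non-convergence, rank deficiency) are
#' excluded and counted in `n_excluded`; the rejection rate uses the
#' denominator `B - n_excluded`.
#'
#' @param model A [simulation_model()].
#' @param design `"nof1"`, `"crossover"` or `"rct"`.
#' @param n Patients per replicate.
#' @param B Number of replicates (default 5000).
#' @param seed Root seed; replicate seeds are derived from it, so calls
#'   with the same root seed reuse identical cohort draws across designs
#'   (common random numbers).
#' @param alpha Significance level.
#' @param adjust_carryover Use the carryover-adjusted test (repeated
#'   measures designs only).
#' @return A one-row data frame (an operating-characteristic record):
#'   design, scenario, n, tau, gamma, p_representative, tau_sub, alpha,
#'   n_reps, n_excluded, rejection_rate, mc_se, seed.
#' @export
#' @examples
#' run_oc(scenario(1, tau = 0.25), "nof1", n = 30, B = 100, seed = 1)
run_oc <- function(model, design = c("nof1", "crossover", "rct"), n,
                   B = 5000, seed = 1L, alpha = 0.05,
                   adjust_carryover = FALSE) {
  design <- match.arg(design)
  stopifnot(inherits(model, "simulation_model"), B >= 1)
  seeds <- .child_seeds(seed, B)
  rej <- 0L; excl <- 0L
  for (b in seq_len(B)) {
    cohort <- simulate_cohort(model, n, seed = seeds[b])
    dat <- extract_design(cohort, design)
    dat <- apply_carryover(dat, model$carryover)
    res <- tryCatch(analyze_trial(dat, adjust_carryover = adjust_carryover,
                                  alpha = alpha),
                    error = function(e) NULL)
    if (is.null(res) || !res$converged || !is.finite(res$p_value)) {
      excl <- excl + 1L
    } else if (res$rejected) rej <- rej + 1L
  }
  .oc_row(model, design, n, B, seed, rej, excl, alpha)
}

#' Power curves over a sample-size or effect-size grid
#'
#' `power_curve()` estimates the rejection rate at each sample size of
#' `n_grid`; `tau_curve()` varies the treatment effect over `tau_grid` at
#' a fixed sample size. Each grid point gets its own derived seed
#' (independent draws across points); calling the same function with the
#' same root seed for a different design reuses identical cohorts at every
#' grid point, the common-random-numbers construction used for fair
#' design comparison.
#'
#' @inheritParams run_oc
#' @param n_grid Increasing vector of sample sizes (default the standard
#'   grid 10–200).
#' @param tau_grid Increasing vector of treatment effects (default
#'   0 to 1 in steps of 0.05).
#' @return A data frame with one operating-characteristic row per grid
#'   point (see [run_oc()]).
#' @export
power_curve <- function(model, design, n_grid = default_n_grid(),
                        B = 5000, seed = 1L, alpha = 0.05,
                        adjust_carryover = FALSE) {
  .check_grid(n_grid, "n_grid")
  seeds <- .child_seeds(seed, length(n_grid))
  do.call(rbind, lapply(seq_along(n_grid), function(j)
    run_oc(model, design, n = n_grid[j], B = B, seed = seeds[j],
           alpha = alpha, adjust_carryover = adjust_carryover)))
}

#' @rdname power_curve
#' @export
tau_curve <- function(model, design, tau_grid = default_tau_grid(), n,
                      B = 5000, seed = 1L, alpha = 0.05,
                      adjust_carryover = FALSE) {
  .check_grid(tau_grid, "tau_grid", strict = FALSE)
  seeds <- .child_seeds(seed, length(tau_grid))
  do.call(rbind, lapply(seq_along(tau_grid), function(j) {
    mj <- model; mj$tau <- tau_grid[j]
    run_oc(mj, design, n = n, B = B, seed = seeds[j], alpha = alpha,
           adjust_carryover = adjust_carryover)
  }))
}

.check_grid <- function(grid, what, strict = TRUE) {
  if (length(grid) == 0 || is.unsorted(grid, strictly = strict))
    stop("`", what, "` must be a non-empty increasing vector",
         call. = FALSE)
  invisible(grid)
}

#' Standard experiment grids
#'
#' The sample-size and effect-size grids used throughout the simulation
#' study: `n = 10, 20, 30, 40, 50, 100, 150, 200` and
#' `tau = 0, 0.05, ..., 1`.
#' @return A numeric vector.
#' @export
default_n_grid <- function() c(10L, 20L, 30L, 40L, 50L, 100L, 150L, 200L)

#' @rdname default_n_grid
#' @export
default_tau_grid <- function() seq(0, 1, by = 0.05)

#' Smallest grid sample size reaching a target power
#'
#' Scans `n_grid` in increasing order and returns the smallest sample
#' size whose estimated power is at least `target_power`. Seeds are
#' derived per grid point exactly as in [power_curve()], so the result
#' agrees with reading the full curve; with `early_stop = TRUE` (default)
#' the scan stops at the first qualifying point.
#'
#' @inheritParams power_curve
#' @param target_power Target in (0, 1), e.g. 0.8.
#' @param early_stop Stop scanning once the target is reached.
#' @return The minimum sample size as an integer, or `NA` if no grid
#'   point qualifies. The estimated curve (scanned portion) is attached
#'   as attribute `"curve"`.
#' @export
min_n_for_power <- function(model, design, target_power = 0.8,
                            n_grid = default_n_grid(), B = 5000,
                            seed = 1L, alpha = 0.05,
                            adjust_carryover = FALSE, early_stop = TRUE) {
  stopifnot(target_power > 0, target_power < 1)
  .check_grid(n_grid, "n_grid")
  seeds <- .child_seeds(seed, length(n_grid))
  rows <- list(); found <- NA_integer_
  for (j in seq_along(n_grid)) {
    rows[[j]] <- run_oc(model, design, n = n_grid[j], B = B,
                        seed = seeds[j], alpha = alpha,
                        adjust_carryover = adjust_carryover)
    if (is.na(found) && isTRUE(rows[[j]]$rejection_rate >= target_power)) {
      found <- as.integer(n_grid[j])
      if (early_stop) break
    }
  }
  structure(found, curve = do.call(rbind, rows))
}

#' Operating characteristics under non-representative sampling
#'
#' Reproduces the selection-bias experiment: each patient belongs to the
#' target population with probability `p` and to a sub-population with a
#' different true treatment effect otherwise, and the hypothesis test is
#' interpreted against the *target* population. In `mode = "type1"` the
#' target has no effect (`tau = 0`) while the sub-population responds
#' (`tau_sub = effect`), so every rejection is a false conclusion about
#' the target population (type-I error). In `mode = "power"` the target
#' responds (`tau = effect`) and the sub-population does not, so the
#' rejection rate is the power for the target population.
#'
#' @inheritParams run_oc
#' @param n Patients per replicate (the experiment's standard size is 30).
#' @param p_grid Increasing vector of representative-sampling
#'   probabilities in `[0, 1]`.
#' @param mode `"type1"` or `"power"` (see above).
#' @param effect Magnitude of the non-null treatment effect
#'   (default 0.25).
#' @return A data frame with one operating-characteristic row per `p`.
#' @export
selection_bias_oc <- function(model, design, n = 30,
                              p_grid = seq(0.1, 1, by = 0.1), B = 5000,
                              seed = 1L, mode = c("type1", "power"),
                              effect = 0.25, alpha = 0.05) {
  mode <- match.arg(mode)
  .check_grid(p_grid, "p_grid")
  if (any(p_grid < 0 | p_grid > 1))
    stop("`p_grid` values must lie in [0, 1]", call. = FALSE)
  seeds <- .child_seeds(seed, length(p_grid))
  do.call(rbind, lapply(seq_along(p_grid), function(j) {
    mj <- model
    mj$p_representative <- p_grid[j]
    if (mode == "type1") { mj$tau <- 0; mj$tau_sub <- effect }
    else { mj$tau <- effect; mj$tau_sub <- 0 }
    run_oc(mj, design, n = n, B = B, seed = seeds[j], alpha = alpha)
  }))
}

#' Random-effect separation of non-representative patients
#'
#' Quantifies how well the repeated measures designs expose patients who
#' do not belong to the target population through their estimated random
#' intercepts. For each replicate a mixed cohort is simulated
#' (`p_representative = p`), the treatment model is fitted to the full
#' N-of-1 data and to the crossover (cycle-1) data extracted from the same
#' draws, and the difference in mean BLUP — sub-population minus
#' representative patients — is recorded for both designs. Replicates in
#' which either group is empty are skipped. The parallel RCT cannot enter
#' this comparison (one observation per patient identifies no random
#' effect).
#'
#' @inheritParams run_oc
#' @param p Representative-sampling probability, strictly between 0
#'   and 1.
#' @param n Patients per replicate (the reference experiment uses 100).
#' @param B Number of replicates (the reference experiment uses 1000).
#' @return A list with class `"re_comparison_pair"` holding two
#'   `"re_comparison"` records (`nof1`, `crossover`), each with fields
#'   `design`, `n_reps`, and `diffs` (one mean-BLUP difference per
#'   retained replicate).
#' @export
compare_random_effects <- function(model, n = 100, p = 0.5, B = 1000,
                                   seed = 1L) {
  stopifnot(inherits(model, "simulation_model"), p > 0, p < 1)
  model$p_representative <- p
  seeds <- .child_seeds(seed, B)
  d_nof1 <- d_xo <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    cohort <- simulate_cohort(model, n, seed = seeds[b])
    rep_ids <- unique(cohort$patient_id[cohort$population == "representative"])
    sub_ids <- unique(cohort$patient_id[cohort$population == "subpopulation"])
    if (length(rep_ids) == 0L || length(sub_ids) == 0L) next
    xo <- extract_design(cohort, "crossover")
    f1 <- tryCatch(fit_random_intercept_ml(cohort), error = function(e) NULL)
    f2 <- tryCatch(fit_random_intercept_ml(xo), error = function(e) NULL)
    if (is.null(f1) || is.null(f2)) next
    d_nof1[b] <- mean(f1$blups[as.character(sub_ids)]) -
      mean(f1$blups[as.character(rep_ids)])
    d_xo[b] <- mean(f2$blups[as.character(sub_ids)]) -
      mean(f2$blups[as.character(rep_ids)])
  }
  keep <- !is.na(d_nof1) & !is.na(d_xo)
  out <- list(
    nof1 = structure(list(design = "nof1", n_reps = as.integer(B),
                          diffs = d_nof1[keep]), class = "re_comparison"),
    crossover = structure(list(design = "crossover", n_reps = as.integer(B),
                               diffs = d_xo[keep]), class = "re_comparison"))
  class(out) <- "re_comparison_pair"
  out
}

#' @export
print.re_comparison <- function(x, ...) {
  cat(sprintf(
    "<re_comparison> %s: %d replicates, mean BLUP difference %.4f (SE %.4f)\n",
    x$design, length(x$diffs), mean(x$diffs),
    stats::sd(x$diffs) / sqrt(length(x$diffs))))
  invisible(x)
}

#' @export
print.re_comparison_pair <- function(x, ...) {
  print(x$nof1); print(x$crossover)
  invisible(x)
}
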