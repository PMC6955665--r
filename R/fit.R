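# Core profiled-ML fit of the random-intercept model on raw vectors.
#
# Marginally, y ~ N(X beta, sigma_eps^2 (I + lambda Z Z')) with
# lambda = sigma_mu^2 / sigma_eps^2 and Z the patient indicator matrix.
# For fixed lambda the GLS estimate of beta and the ML estimate of
# sigma_eps^2 are available in closed form through per-patient sums
# (V_i^{-1} = I - c_i J with c_i = lambda / (1 + lambda m_i)), so the ML
# problem reduces to a bounded 1-D search over log(lambda).
# tiny-system solver: the design has at most 3 columns
.solve_small <- function(A, b) {
  p <- length(b)
  if (p == 1L) return(b / A[1L])
  if (p == 2L) {
    d <- A[1L] * A[4L] - A[2L] * A[3L]
    return(c(A[4L] * b[1L] - A[3L] * b[2L],
             A[1L] * b[2L] - A[2L] * b[1L]) / d)
  }
  solve(A, b)
}

.ri_core <- function(y, X, g, m) {
  N <- length(y)
  S <- rowsum.default(X, g, reorder = TRUE)        # per-patient colsums of X
  t_ <- rowsum.default(y, g, reorder = TRUE)[, 1L] # per-patient sums of y
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1L]
  yty <- sum(y * y)

  profile_dev <- function(loglam) {
    lam <- exp(loglam)
    cc <- lam / (1 + lam * m)
    A <- XtX - crossprod(S, S * cc)
    ct <- cc * t_
    b <- Xty - crossprod(S, ct)[, 1L]
    beta <- .solve_small(A, b)
    rss <- yty - sum(ct * t_) - sum(beta * b)
    s2 <- if (rss > N * 1e-12) rss / N else 1e-12
    N * log(2 * pi * s2) + sum(log1p(lam * m)) + N
  }

  lo <- log(1e-10); hi <- log(1e10)
  opt <- stats::optimize(profile_dev, c(lo, hi), tol = 1e-9)
  dev_lo <- profile_dev(lo)                        # boundary sigma_mu^2 -> 0
  loglam <- if (dev_lo <= opt$objective) lo else opt$minimum
  lam <- exp(loglam)

  cc <- lam / (1 + lam * m)
  A <- XtX - crossprod(S, S * cc)
  ct <- cc * t_
  b <- Xty - crossprod(S, ct)[, 1L]
  beta <- .solve_small(A, b)
  rss <- yty - sum(ct * t_) - sum(beta * b)
  s2 <- if (rss > N * 1e-12) rss / N else 1e-12
  dev <- N * log(2 * pi * s2) + sum(log1p(lam * m)) + N
  blup <- cc * (t_ - drop(S %*% beta))             # E[b_i | y, theta-hat]
  var_patient <- if (loglam <= lo) 0 else lam * s2
  list(beta = beta, var_patient = var_patient, var_error = s2,
       deviance = dev, blup = blup, lambda = lam,
       converged = is.finite(dev))
}

.design_matrix <- function(data, include_treatment, include_carryover) {
  X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
  if (include_treatment) X <- cbind(X, treatment = data$treatment)
  if (include_carryover) X <- cbind(X, prev_treated = data$prev_treated)
  X
}

#' Maximum-likelihood fit of the random-intercept model
#'
#' Fits \eqn{Y = X\beta + b_i + \epsilon}, \eqn{b_i \sim N(0,
#' \sigma_\mu^2)}, \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)} by full
#' maximum likelihood (not REML, so that deviance differences between
#' nested fixed-effect models are valid likelihood-ratio statistics).
#' \eqn{\beta} and \eqn{\sigma_\epsilon^2} are profiled out analytically
#' and the likelihood is maximized over the variance ratio
#' \eqn{\lambda = \sigma_\mu^2 / \sigma_\epsilon^2} by bounded search on
#' the log scale (\eqn{\lambda \in [10^{-10}, 10^{10}]}, tolerance
#' \eqn{10^{-9}}); the \eqn{\sigma_\mu^2 = 0} boundary is always examined.
#' Random-intercept predictions are the empirical-Bayes conditional means
#' (BLUPs) \eqn{\hat b_i = \hat c_i \sum_k \hat r_{ik}} with
#' \eqn{\hat c_i = \hat\lambda / (1 + \hat\lambda m_i)}.
#'
#' @param data A `"trial_data"` object (or data frame) with at least two
#'   observations per patient — N-of-1 or crossover data. Single-period
#'   RCT data cannot identify \eqn{\sigma_\mu^2}; use [fit_ols()].
#' @param include_treatment Include the treatment fixed effect.
#' @param include_carryover_covariate Include `prev_treated` as an
#'   additional binary fixed effect (the carryover-adjusted analysis).
#' @return An object of class `"ri_fit"`: list with `fixed_effects`
#'   (named vector), `var_patient`, `var_error`, `deviance`
#'   (\eqn{-2 \times} maximized ML log-likelihood), `blups` (named by
#'   patient id), `lambda`, `n_obs`, `n_patients`, `converged`.
#' @export
#' @examples
#' d <- simulate_cohort(scenario(1), n = 10, seed = 1)
#' fit <- fit_random_intercept_ml(d)
#' fit$fixed_effects
fit_random_intercept_ml <- function(data, include_treatment = TRUE,
                                    include_carryover_covariate = FALSE) {
  y <- data$outcome
  pid <- data$patient_id
  ids <- unique(pid)
  g <- match(pid, ids)
  m <- tabulate(g)
  if (any(m < 2L))
    stop("every patient needs >= 2 observations to fit the random-",
         "intercept model; analyze single-period (RCT) data with fit_ols()",
         call. = FALSE)
  X <- .design_matrix(data, include_treatment, include_carryover_covariate)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  core <- .ri_core(y, X, g, m)
  structure(
    list(fixed_effects = stats::setNames(core$beta, colnames(X)),
         var_patient = core$var_patient, var_error = core$var_error,
         deviance = core$deviance,
         blups = stats::setNames(core$blup, ids),
         lambda = core$lambda, n_obs = length(y),
         n_patients = length(ids), converged = core$converged),
    class = "ri_fit")
}

#' @export
print.ri_fit <- function(x, ...) {
  cat(sprintf("<ri_fit> %d obs / %d patients, deviance %.6f\n",
              x$n_obs, x$n_patients, x$deviance))
  print(round(x$fixed_effects, 6))
  cat(sprintf("  var_patient = %.6g, var_error = %.6g\n",
              x$var_patient, x$var_error))
  invisible(x)
}

.new_test <- function(statistic, p_value, alpha, method, estimate,
                      converged = TRUE) {
  structure(list(statistic = statistic, p_value = p_value,
                 rejected = is.finite(p_value) && p_value < alpha,
                 alpha = alpha, method = method, estimate = estimate,
                 converged = converged),
            class = "design_test")
}

#' @export
print.design_test <- function(x, ...) {
  cat(sprintf("<design_test> %s: statistic = %.4f, p = %.4g (%s at alpha = %g)\n",
              x$method, x$statistic, x$p_value,
              if (x$rejected) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Deviance likelihood-ratio test of the treatment effect
#'
#' Fits the intercept-only and the intercept-plus-treatment
#' random-intercept models by ML on the same data and refers the deviance
#' difference to a \eqn{\chi^2_1} distribution, the treatment effect being
#' a single fixed-effect parameter. When `adjust_carryover` is `TRUE`
#' *both* models additionally contain the `prev_treated` fixed effect, so
#' the test keeps one degree of freedom.
#'
#' @param data N-of-1 or crossover `"trial_data"`.
#' @param adjust_carryover Adjust both models for previous-period
#'   treatment.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `"design_test"` object: `statistic` (deviance difference,
#'   clipped below at 0), `p_value`, `rejected`, `alpha`,
#'   `method = "lrt_chisq1"`, `estimate` (treatment coefficient of the
#'   alternative model), `converged`.
#' @export
lrt_treatment <- function(data, adjust_carryover = FALSE, alpha = 0.05) {
  f1 <- fit_random_intercept_ml(data, include_treatment = TRUE,
                                include_carryover_covariate = adjust_carryover)
  f0 <- fit_random_intercept_ml(data, include_treatment = FALSE,
                                include_carryover_covariate = adjust_carryover)
  stat <- max(0, f0$deviance - f1$deviance)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  .new_test(stat, p, alpha, "lrt_chisq1",
            estimate = unname(f1$fixed_effects["treatment"]),
            converged = f0$converged && f1$converged)
}

#' Ordinary-least-squares analysis of the parallel RCT
#'
#' Regresses the single outcome per patient on an intercept and the
#' treatment indicator with [stats::lm()] and tests the treatment
#' coefficient two-sided with the usual t statistic.
#'
#' @param data RCT `"trial_data"` (one record per patient, both arms
#'   non-empty).
#' @param alpha Significance level (default 0.05).
#' @return A `"design_test"` with `method = "ols_wald"`, `statistic`
#'   = |t|, and the treatment-effect `estimate`.
#' @export
fit_ols <- function(data, alpha = 0.05) {
  if (length(unique(data$treatment)) < 2L)
    stop("both arms must contain at least one patient", call. = FALSE)
  fit <- stats::lm(outcome ~ treatment, data = data)
  co <- suppressWarnings(summary(fit))$coefficients
  .new_test(abs(co["treatment", "t value"]),
            co["treatment", "Pr(>|t|)"], alpha, "ols_wald",
            estimate = unname(co["treatment", "Estimate"]))
}

#' Analyze a trial dataset with its design's standard test
#'
#' Dispatches to [lrt_treatment()] for N-of-1 and crossover data and to
#' [fit_ols()] for parallel RCT data.
#'
#' @inheritParams lrt_treatment
#' @return A `"design_test"`.
#' @export
analyze_trial <- function(data, adjust_carryover = FALSE, alpha = 0.05) {
  if (identical(attr(data, "design"), "rct")) fit_ols(data, alpha = alpha)
  else lrt_treatment(data, adjust_carryover = adjust_carryover, alpha = alpha)
}

#' Serialize a fit or test result to a JSON record
#'
#' `"ri_fit"` objects are written with deviance reported to 6 decimal
#' places; `"design_test"` objects record statistic, p-value, decision and
#' method.
#'
#' @param x An `"ri_fit"` or `"design_test"` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
to_json <- function(x, path = NULL) {
  rec <- if (inherits(x, "ri_fit")) {
    list(fixed_effects = as.list(x$fixed_effects),
         var_patient = x$var_patient, var_error = x$var_error,
         deviance = round(x$deviance, 6), blups = as.list(x$blups),
         n_obs = x$n_obs, n_patients = x$n_patients,
         converged = x$converged)
  } else if (inherits(x, "design_test")) {
    list(statistic = x$statistic, p_value = x$p_value,
         rejected = x$rejected, alpha = x$alpha, method = x$method,
         estimate = x$estimate)
  } else stop("no JSON serialization for class ",
              paste(class(x), collapse = "/"), call. = FALSE)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
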