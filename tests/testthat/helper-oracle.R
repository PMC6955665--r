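# Brute-force ML oracle for the random-intercept model, kept deliberately
# independent of the package's profiled fitter: the -2 log-likelihood is
# evaluated from the dense per-patient covariance matrix
# sigma_eps^2 I + sigma_mu^2 J via its Cholesky factor, and maximized by
# Nelder-Mead over (beta, log sigma_mu, log sigma_eps) from several starts
# with a polishing restart.
oracle_neg2ll <- function(par, y, X, pid) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sm2 <- exp(2 * par[p + 1L])
  se2 <- exp(2 * par[p + 2L])
  r <- y - drop(X %*% beta)
  tot <- 0
  for (id in unique(pid)) {
    ri <- r[pid == id]
    Sig <- diag(se2, length(ri)) + sm2
    ch <- chol(Sig)
    z <- backsolve(ch, ri, transpose = TRUE)
    tot <- tot + length(ri) * log(2 * pi) + 2 * sum(log(diag(ch))) +
      sum(z * z)
  }
  tot
}

oracle_fit <- function(data, include_treatment = TRUE,
                       include_carryover = FALSE) {
  y <- data$outcome
  X <- cbind(`(Intercept)` = 1,
             if (include_treatment) cbind(treatment = data$treatment),
             if (include_carryover) cbind(prev_treated = data$prev_treated))
  ols <- stats::lm.fit(X, y)
  s0 <- max(stats::sd(ols$residuals), 1e-3)
  best <- NULL
  for (sm0 in c(1e-4, 0.3, 1) * s0) {
    par0 <- c(ols$coefficients, log(sm0), log(s0))
    o <- stats::optim(par0, oracle_neg2ll, y = y, X = X,
                      pid = data$patient_id, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
    o <- stats::optim(o$par, oracle_neg2ll, y = y, X = X,
                      pid = data$patient_id, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(deviance = best$value,
       beta = stats::setNames(best$par[seq_len(ncol(X))], colnames(X)),
       sigma_mu = exp(best$par[ncol(X) + 1L]),
       sigma_eps = exp(best$par[ncol(X) + 2L]))
}

# hand-built noise-free N-of-1 patient with a given treatment sequence
make_patient <- function(treatment, tau = 0.25, mu_i = 0,
                         design = "nof1") {
  nc <- length(treatment) / 2L
  df <- data.frame(
    patient_id = 1L,
    cycle = rep(seq_len(nc), each = 2L),
    look = rep(c(1L, 2L), nc),
    treatment = as.integer(treatment),
    outcome = mu_i + tau * treatment,
    prev_treated = c(0L, treatment[-length(treatment)]),
    population = "representative")
  structure(df, design = design, class = c("trial_data", "data.frame"))
}

# rejection-rate expectation at the Monte-Carlo tolerance 3 * mc_se
expect_rate <- function(oc, target, label = NULL) {
  lab <- label %||% sprintf("%s sc%s n=%s gamma=%s p=%s", oc$design,
                            oc$scenario, oc$n, oc$gamma,
                            oc$p_representative)
  expect_lt(abs(oc$rejection_rate - target), 3 * oc$mc_se + 1e-12,
            label = sprintf("%s: |%.4f - %.3f| (3 mc_se = %.4f)",
                            lab, oc$rejection_rate, target, 3 * oc$mc_se))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
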