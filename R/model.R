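#' Generative model for a simulated trial cohort
#'
#' Bundles every parameter of the random-intercept data-generating model
#' \deqn{Y_{ick} = \mu_i + \tau Z_{ick} + \epsilon_{ick},} with
#' \eqn{\mu_i \sim N(\mu, \sigma_\mu^2)} and
#' \eqn{\epsilon_{ick} \sim N(0, \sigma_\epsilon^2)}, where \eqn{Z_{ick}}
#' indicates treatment for patient \eqn{i} in cycle \eqn{c} at look
#' \eqn{k = 1, 2}. Each cycle contains exactly two looks, one under each
#' condition, in randomized order.
#'
#' For non-representative-sampling (selection-bias) experiments each patient
#' is drawn from the target population with probability `p_representative`
#' (treatment effect `tau`) and otherwise from a sub-population with
#' treatment effect `tau_sub`; both groups share the same variance
#' components.
#'
#' @param mu Grand mean of the outcome (default 0; operating
#'   characteristics are invariant to it because the intercept is always
#'   estimated).
#' @param tau Treatment effect for the target population, in outcome units.
#' @param sigma_mu Between-patient standard deviation (\eqn{\sigma_\mu});
#'   must be nonnegative.
#' @param sigma_eps Residual standard deviation (\eqn{\sigma_\epsilon});
#'   must be strictly positive.
#' @param n_cycles Number of treatment/placebo cycles per patient
#'   (default 3).
#' @param carryover Additive carryover increment \eqn{\gamma \ge 0} applied
#'   to any outcome whose immediately preceding period, in the design's own
#'   chronology, was a treatment period. See [apply_carryover()].
#' @param p_representative Probability that a patient is sampled from the
#'   target population; in `[0, 1]`.
#' @param tau_sub Treatment effect of the sub-population (used when
#'   `p_representative < 1`).
#' @param resample_order_each_cycle If `TRUE` (default) the within-cycle
#'   treatment order is re-randomized independently for every patient-cycle;
#'   if `FALSE` each patient keeps the order of their first cycle.
#'
#' @return An object of class `"simulation_model"`: a validated list of the
#'   above parameters plus `looks_per_cycle = 2` and a `scenario` id
#'   (`NA` unless built by [scenario()]).
#' @seealso [scenario()] for the four named variance structures,
#'   [simulate_cohort()].
#' @export
#' @examples
#' m <- simulation_model(tau = 0.25, sigma_mu = 0.1, sigma_eps = 0.5)
#' m
simulation_model <- function(mu = 0, tau = 0.25, sigma_mu = 0.1,
                             sigma_eps = 0.5, n_cycles = 3L,
                             carryover = 0, p_representative = 1,
                             tau_sub = 0,
                             resample_order_each_cycle = TRUE) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(tau_sub), length(tau_sub) == 1L, is.finite(tau_sub))
  if (!is.numeric(sigma_mu) || length(sigma_mu) != 1L || sigma_mu < 0)
    stop("`sigma_mu` must be a nonnegative number", call. = FALSE)
  if (!is.numeric(sigma_eps) || length(sigma_eps) != 1L || sigma_eps <= 0)
    stop("`sigma_eps` must be a positive number", call. = FALSE)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L ||
      n_cycles < 1 || n_cycles != round(n_cycles))
    stop("`n_cycles` must be a positive integer", call. = FALSE)
  if (!is.numeric(carryover) || length(carryover) != 1L || carryover < 0)
    stop("`carryover` must be a nonnegative number", call. = FALSE)
  if (!is.numeric(p_representative) || length(p_representative) != 1L ||
      p_representative < 0 || p_representative > 1)
    stop("`p_representative` must lie in [0, 1]", call. = FALSE)
  structure(
    list(mu = mu, tau = tau, sigma_mu = sigma_mu, sigma_eps = sigma_eps,
         n_cycles = as.integer(n_cycles), looks_per_cycle = 2L,
         carryover = carryover, p_representative = p_representative,
         tau_sub = tau_sub,
         resample_order_each_cycle = isTRUE(resample_order_each_cycle),
         scenario = NA_integer_),
    class = "simulation_model"
  )
}

# (sigma_mu, sigma_eps) for the four named variance structures
.scenario_sd <- matrix(c(0.1, 0.5,
                         0,   0.5,
                         0.5, 0.5,
                         0.5, 1), ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("sigma_mu", "sigma_eps")))

#' Named variance-structure scenarios
#'
#' Factory for the four standard variance structures used throughout the
#' simulation study:
#' \describe{
#'   \item{1}{weak heterogeneity, moderate error:
#'     \eqn{\sigma_\mu = 0.1, \sigma_\epsilon = 0.5}}
#'   \item{2}{homogeneity, moderate error:
#'     \eqn{\sigma_\mu = 0, \sigma_\epsilon = 0.5}}
#'   \item{3}{strong heterogeneity, moderate error:
#'     \eqn{\sigma_\mu = 0.5, \sigma_\epsilon = 0.5}}
#'   \item{4}{strong heterogeneity, large error:
#'     \eqn{\sigma_\mu = 0.5, \sigma_\epsilon = 1}}
#' }
#'
#' @param id Scenario number, 1 to 4.
#' @param ... Further arguments passed to [simulation_model()]
#'   (e.g. `tau`, `carryover`, `p_representative`).
#' @return A `"simulation_model"` with the scenario's variance components
#'   and its `scenario` field set.
#' @export
#' @examples
#' scenario(4, tau = 0.25)$sigma_eps  # 1
scenario <- function(id, ...) {
  if (!is.numeric(id) || length(id) != 1L || !id %in% 1:4)
    stop("scenario `id` must be 1, 2, 3 or 4", call. = FALSE)
  m <- simulation_model(sigma_mu = .scenario_sd[id, 1L],
                        sigma_eps = .scenario_sd[id, 2L], ...)
  m$scenario <- as.integer(id)
  m
}

#' @export
print.simulation_model <- function(x, ...) {
  cat("<simulation_model>",
      if (!is.na(x$scenario)) sprintf(" scenario %d", x$scenario), "\n",
      sep = "")
  cat(sprintf("  mu = %g, tau = %g, sigma_mu = %g, sigma_eps = %g\n",
              x$mu, x$tau, x$sigma_mu, x$sigma_eps))
  cat(sprintf("  cycles = %d x %d looks, carryover = %g\n",
              x$n_cycles, x$looks_per_cycle, x$carryover))
  if (x$p_representative < 1)
    cat(sprintf("  mixture: p_representative = %g, tau_sub = %g\n",
                x$p_representative, x$tau_sub))
  invisible(x)
}

#' Sample sizes at which the aggregated N-of-1 design attains 80% power
#'
#' The fixed per-scenario sample sizes used by the effect-size
#' (power-versus-tau) and type-I-error experiments. They are the smallest
#' grid sample sizes at which the N-of-1 design reaches 80% power for
#' \eqn{\tau = 0.25} under the given carryover increment, as found by
#' [min_n_for_power()] on the standard grid
#' `c(10, 20, 30, 40, 50, 100, 150, 200)`.
#'
#' @param scenario_id Scenario number(s) in 1–4.
#' @param gamma Carryover increment: one of 0, 0.05, 0.1, 0.15.
#' @return Integer vector of sample sizes, one per `scenario_id`.
#' @export
#' @examples
#' power80_n(1:4)            # 30  30  30 100
#' power80_n(1, gamma = 0.1) # 40
power80_n <- function(scenario_id, gamma = 0) {
  stopifnot(all(scenario_id %in% 1:4))
  tab <- switch(as.character(gamma),
                "0"    = c(30L, 30L, 30L, 100L),
                "0.05" = c(30L, 30L, 30L, 150L),
                "0.1"  = c(40L, 40L, 40L, 150L),
                "0.15" = c(50L, 50L, 100L, 200L),
                stop("no tabulated sample sizes for gamma = ", gamma,
                     call. = FALSE))
  tab[scenario_id]
}
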