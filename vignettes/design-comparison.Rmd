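---
title: "Comparing aggregated N-of-1, crossover and parallel designs by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing aggregated N-of-1, crossover and parallel designs by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

An aggregated N-of-1 trial pools many within-patient multi-crossover
trials: each participant alternates between a new therapy and placebo over
several cycles, and the patient series are analyzed jointly. How do the
operating characteristics of such a trial — power, type-I error, and their
degradation under carryover effects and non-representative sampling —
compare with a conventional two-period crossover trial and a parallel
randomized controlled trial (RCT) run on the same patients? nof1sim
answers this by Monte-Carlo simulation: it generates cohorts from an
explicit linear mixed model, derives all three designs from the *same*
outcome draws, and estimates rejection rates of each design's standard
analysis over thousands of replicates.

## Generative model

For patient $i$, cycle $c = 1, \dots, C$ (default $C = 3$) and look
$k = 1, 2$ within a cycle,

$$Y_{ick} = \mu_i + \tau\, Z_{ick} + \epsilon_{ick}, \qquad
  \mu_i \sim N(\mu, \sigma_\mu^2), \quad
  \epsilon_{ick} \sim N(0, \sigma_\epsilon^2),$$

where $Z_{ick}$ is the treatment indicator. Each cycle contains exactly
one treated and one placebo look; which comes first is randomized with
probability $1/2$, independently for every patient-cycle. Four named
variance structures are built in via `scenario()`:

| scenario | $\sigma_\mu$ | $\sigma_\epsilon$ | interpretation |
|---|---|---|---|
| 1 | 0.1 | 0.5 | weak heterogeneity, moderate error |
| 2 | 0   | 0.5 | homogeneity, moderate error |
| 3 | 0.5 | 0.5 | strong heterogeneity, moderate error |
| 4 | 0.5 | 1   | strong heterogeneity, large error |

$\tau = 0.25$ is treated as a moderate effect throughout; the grand mean
defaults to $\mu = 0$ because the intercept is always estimated, so every
operating characteristic is invariant to it.

The three designs are nested views of one simulated cohort
(`extract_design()`): the N-of-1 dataset keeps all $2C$ periods, the
crossover dataset keeps the two periods of cycle 1, and the RCT keeps one
cycle-1 period per patient chosen with equal probability — outcome and
treatment label together, never re-drawn. This common-random-numbers
construction means observed design differences are differences between
designs, not between simulation runs.

```{r}
library(nof1sim)
model  <- scenario(1, tau = 0.25)
cohort <- simulate_cohort(model, n = 30, seed = 1)
xo     <- extract_design(cohort, "crossover")
rct    <- extract_design(cohort, "rct")
```

## Inference

The repeated measures designs are analyzed with the random-intercept
model $Y = X\beta + b_i + \epsilon$, $b_i \sim N(0, \sigma_\mu^2)$,
fitted by full maximum likelihood — *not* REML, because the treatment
test is a deviance difference between models with different fixed
effects, which is valid only under ML. `lrt_treatment()` fits the
intercept-only and intercept-plus-treatment models and refers

$$\Lambda = \mathrm{dev}_0 - \mathrm{dev}_1$$

to $\chi^2_1$ at $\alpha = 0.05$ (two-sided by construction). The
parallel RCT, with one observation per patient, cannot identify
$\sigma_\mu^2$ and is analyzed by ordinary least squares with the usual
two-sided t test (`fit_ols()`).

`fit_random_intercept_ml()` profiles $\beta$ and $\sigma_\epsilon^2$ out
analytically — per-patient sufficient statistics make
$V^{-1} = I - \frac{\lambda}{1 + \lambda m_i} J$ closed-form — and
maximizes over the single variance ratio
$\lambda = \sigma_\mu^2 / \sigma_\epsilon^2$ by bounded search on the log
scale. Random-effect predictions are the empirical-Bayes conditional
means (BLUPs)
$\hat b_i = \frac{\hat\lambda}{1 + \hat\lambda m_i} \sum_k \hat r_{ik}$,
which shrink each patient's mean residual toward zero.

### Numerical choices

* $\lambda$ is searched in $[10^{-10}, 10^{10}]$ (log scale, tolerance
  $10^{-9}$), and the $\sigma_\mu^2 = 0$ boundary is always evaluated
  explicitly; if it wins, `var_patient` is reported as exactly 0 and the
  deviance coincides with the OLS $-2\log L$ (a tested identity).
* The profiled $\hat\sigma_\epsilon^2$ is floored at $10^{-12}$ so that
  degenerate (constant-outcome) data yield a finite deviance instead of a
  failure.
* The LRT statistic is clipped below at 0: the nested deviances satisfy
  $\mathrm{dev}_0 \ge \mathrm{dev}_1$ mathematically, and clipping removes
  the $\sim 10^{-9}$ optimizer noise around equality.
* No boundary-mixture (50:50 $\chi^2$) correction is applied: the tested
  parameter is a fixed effect, not a variance component.
* Replicates whose analysis fails are excluded and counted
  (`n_excluded`); rejection rates use the reduced denominator. With the
  profiled fitter the exclusion rate is zero in all standard settings.
* The fit's "deviance" is the marginal ML deviance,
  $-2 \log L(\hat\beta, \hat\lambda, \hat\sigma_\epsilon^2)$. A
  conditional (random-effect-penalized) accounting would change both
  model deviances by the same kind of term; the marginal difference is
  the classical LRT and is what the package uses.

The fitter is verified two ways in the test suite: against a brute-force
maximizer of the dense multivariate-normal likelihood over
$(\beta, \log\sigma_\mu, \log\sigma_\epsilon)$ (agreement to $10^{-5}$ in
deviance on small cohorts), and against `lme4::lmer(..., REML = FALSE)`.
lme4 is used only as a cross-check, never as the implementation.

## Carryover effects

`apply_carryover()` adds a fixed increment $\gamma$ to every outcome
whose immediately preceding period — in the receiving design's own
chronology — was a treated period. Consequences per design:

* **N-of-1**: carryover acts within cycles (treatment-first raises the
  following placebo look) and across cycle boundaries (treatment in look
  2 raises the first look of the next cycle, whichever condition it is).
* **Crossover**: only treatment-first patients are affected, on their
  placebo period.
* **RCT**: single period per patient, never affected.

Two readings were genuinely open. First, *when* carryover is applied: the
package applies it after design extraction, using each design's own
period sequence, because the per-design descriptions above are mutually
inconsistent with inheriting the N-of-1 chronology. Second,
*compounding*: a period following two consecutive treated periods still
receives a single $+\gamma$ — the increment models the residual effect of
the immediately previous exposure only. No washout periods are modeled;
$\gamma$ is exactly the bias a washout would remove.

The carryover-adjusted analysis (`adjust_carryover = TRUE`) adds the
binary previous-period-treated covariate to *both* LRT models, keeping
the test at one degree of freedom. In the package's experiments this
adjustment restores the type-I error to its nominal level under
carryover (the unadjusted test inflates, increasingly in $\gamma$ and
$n$) at no material cost in power relative to the unadjusted test — the
property the test suite asserts.

## Non-representative sampling

`selection_bias_oc()` models selection bias as a per-patient mixture:
with probability $p$ a patient comes from the target population, with
$1 - p$ from a sub-population whose treatment effect differs. Both groups
share $(\sigma_\mu, \sigma_\epsilon)$; only $\tau$ differs — the sampling
label is drawn before the patient intercept. In `type1` mode the target
has $\tau = 0$ and the sub-population responds ($\tau_{sub} = 0.25$), so
any rejection is a false population-level conclusion; in `power` mode the
roles are swapped. Because repeated measures multiply each patient's
influence, the N-of-1 design is the most sensitive to contamination —
and, symmetrically, best at exposing it: `compare_random_effects()`
records, per replicate, the difference in mean BLUP between
sub-population and target patients under the N-of-1 and crossover fits of
the same cohort.

## Experiment drivers and reproducibility

`run_oc()` estimates one rejection rate; `power_curve()`, `tau_curve()`,
`min_n_for_power()` and `selection_bias_oc()` sweep the standard grids
($n \in \{10, 20, 30, 40, 50, 100, 150, 200\}$,
$\tau \in \{0, 0.05, \dots, 1\}$). Every driver takes one root seed and
derives an independent child seed per replicate (and per grid point), so
results are bit-for-bit reproducible, any replicate can be re-run in
isolation, and two designs run with the same root seed see identical
cohorts. Monte-Carlo uncertainty is reported as
$\sqrt{\hat\pi(1 - \hat\pi)/B}$ per estimate.

`experiment_config()` + `run_experiment()` (or the CLI wrapper in
`inst/cli/nof1sim.R`) orchestrate full experiments and write a results
CSV (full double precision, exact round trip), a JSON manifest and a log.
Defaults follow the reference settings: $C = 3$, $\tau = 0.25$,
$\alpha = 0.05$, $B = 5000$ replicates, and fixed per-scenario sample
sizes `power80_n()` — the smallest grid sizes at which the N-of-1 design
reaches 80% power, per carryover level.

### Problem sizes used by the shipped checks

The packaged tests estimate every reported operating characteristic with
$B = 2000$ replicates and compare at three Monte-Carlo standard errors;
structural properties (calibration, monotonicity, design ordering) use
$B = 400$–$800$. The acceptance script uses $B = 2000$ per rate and
$B = 5000$ per grid point for the minimum-sample-size search, the
reference replicate count, because that target is an argmin over a grid
with one near-boundary point rather than a rate.

## What the generator does and does not emulate

The simulator reproduces the generative assumptions of the reference
analysis: Gaussian outcomes, a single random intercept, an instantaneous
homogeneous treatment effect, carryover as a fixed additive increment,
and independent errors. Real N-of-1 series typically also exhibit
autocorrelated residuals, time trends, missing observations, varying
block lengths and washout periods, none of which are modeled — so
passing checks validate the comparison of designs *under this model*,
not robustness of any design to those complications. Within-cycle order
can optionally be held fixed per patient
(`resample_order_each_cycle = FALSE`) since the reference description
does not pin this down; the default re-randomizes each cycle.

## Known limitations

* Single random intercept only: no random treatment slopes, crossed or
  nested factors, or AR(1) residuals.
* The mixture model of selection bias shifts only $\tau$; baseline-risk
  (intercept) contamination is not separately modeled.
* The asymptotic $\chi^2_1$ reference makes the mixed-model tests
  slightly anticonservative at very small $n$ (visible as crossover
  empirical size up to $\approx 0.07$ at $n = 30$, matching the
  reference results); no small-sample correction is applied, by design.
* Inference *between* designs (testing power differences) is out of
  scope; curves share cohorts, so eyeballing differences is already
  conservative.
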