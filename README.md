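# nof1sim

Simulation-based operating characteristics of aggregated N-of-1 trials
versus crossover and parallel randomized controlled trials.

## The problem

Aggregated N-of-1 trials pool many within-patient multi-crossover series:
each participant alternates between a new therapy and placebo across
several cycles, and all series are analyzed jointly with a mixed model.
Proponents argue they reach a given power with far fewer patients than a
parallel RCT; skeptics point at carryover effects and non-representative
samples, both of which repeated within-patient measurement amplifies.
`nof1sim` is for trial statisticians and methodologists who want those
trade-offs quantified under an explicit generative model before
committing to a design.

Outcomes are generated from a random-intercept linear mixed model

    Y_ick = mu_i + tau * Z_ick + eps_ick,
    mu_i ~ N(mu, sigma_mu^2),  eps_ick ~ N(0, sigma_eps^2),

for patient i, cycle c = 1..3 and look k = 1,2 (one treated, one placebo
per cycle, in randomized order). From each simulated cohort three designs
are derived from the *same* draws: the full N-of-1 dataset, a two-period
crossover (cycle 1), and a parallel RCT (one random cycle-1 period per
patient). N-of-1 and crossover data are analyzed with a
maximum-likelihood random-intercept fit and the deviance likelihood-ratio
chi-squared(1) test of `tau`; the RCT with ordinary least squares. Monte
Carlo drivers estimate power and type-I error over sample-size,
effect-size, carryover and selection-bias grids, and compare
empirical-Bayes random-intercept predictions (BLUPs) between
representative and non-representative patients. Four standard variance
scenarios `(sigma_mu, sigma_eps) = (0.1, 0.5), (0, 0.5), (0.5, 0.5),
(0.5, 1)` are built in.

## Worked example

```r
library(nof1sim)
model <- scenario(1, tau = 0.25)          # weak heterogeneity, moderate error

oc <- rbind(run_oc(model, "nof1",      n = 30, B = 2000, seed = 42),
            run_oc(model, "crossover", n = 30, B = 2000, seed = 42),
            run_oc(model, "rct",       n = 30, B = 2000, seed = 42))
oc[, c("design", "scenario", "n", "tau", "rejection_rate", "mc_se")]
#>      design scenario  n  tau rejection_rate       mc_se
#> 1      nof1        1 30 0.25         0.9140 0.006269131
#> 2 crossover        1 30 0.25         0.4950 0.011179781
#> 3       rct        1 30 0.25         0.2525 0.009714519
```

Thirty patients give the aggregated N-of-1 analysis 91% power to detect
the moderate effect `tau = 0.25`, versus 50% for the crossover and 25%
for the parallel RCT on the *same* simulated patients (identical root
seed, so identical cohorts across the three calls); `mc_se` is the Monte
Carlo standard error of each estimate over the 2000 replicates.

A single cohort can be inspected and analyzed directly:

```r
cohort <- simulate_cohort(model, n = 30, seed = 1)
fit_random_intercept_ml(cohort)
#> <ri_fit> 180 obs / 30 patients, deviance 254.064938
#> (Intercept)   treatment
#>    0.013406    0.224714
#>   var_patient = 0.0169509, var_error = 0.225734
lrt_treatment(cohort)
#> <design_test> lrt_chisq1: statistic = 9.7430, p = 0.0018 (rejected at alpha = 0.05)
```

Carryover and selection-bias experiments follow the same pattern:

```r
run_oc(scenario(1, tau = 0, carryover = 0.1), "nof1", n = 40, B = 2000, seed = 1)
selection_bias_oc(scenario(1), "nof1", n = 30, p_grid = c(0.5, 0.7, 1),
                  B = 2000, seed = 1, mode = "type1")
min_n_for_power(scenario(1, tau = 0.25), "nof1", target_power = 0.8, B = 2000, seed = 1)
```

Full file-producing experiments are configured with
`experiment_config()` (or a YAML file) and run with `run_experiment()`;
a thin command-line wrapper with `simulate` / `fit` / `run` / `plot`
verbs lives at `inst/cli/nof1sim.R`. The methods vignette
(`vignettes/design-comparison.Rmd`) documents the model, the profiled
likelihood, and every numerical and design choice.

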