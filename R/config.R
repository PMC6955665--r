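.experiments <- c("power_vs_n", "power_vs_tau", "carryover",
                  "selection_bias_type1", "selection_bias_power",
                  "random_effects")
.designs <- c("nof1", "crossover", "rct")

#' Validated configuration for a full simulation experiment
#'
#' Collects everything [run_experiment()] needs: which experiment to run,
#' which variance scenarios and designs to include, the grids, the number
#' of Monte-Carlo replicates and the root seed. Defaults reproduce the
#' reference study settings (3 cycles, \eqn{\tau = 0.25},
#' \eqn{\alpha = 0.05}, B = 5000, standard grids).
#'
#' @param experiment One of `"power_vs_n"`, `"power_vs_tau"`,
#'   `"carryover"`, `"selection_bias_type1"`, `"selection_bias_power"`,
#'   `"random_effects"`.
#' @param scenarios Scenario ids, subset of 1:4.
#' @param designs Designs to run, subset of `c("nof1", "crossover",
#'   "rct")` (`random_effects` always uses nof1 + crossover).
#' @param n_grid,tau_grid,p_grid Grids for the corresponding experiments.
#' @param n Fixed sample size(s) for the fixed-n experiments
#'   (`power_vs_tau`, selection bias, `random_effects`): either one value
#'   or one per scenario. `NULL` picks the study defaults — [power80_n()]
#'   for `power_vs_tau`, 30 for selection bias, 100 for `random_effects`.
#' @param tau Treatment effect for power experiments.
#' @param gamma Carryover increment (used by `carryover` and
#'   `power_vs_tau`).
#' @param p Representative-sampling probability for `random_effects`.
#' @param B Replicates per grid point.
#' @param seed Root RNG seed.
#' @param alpha Significance level.
#' @param adjust_carryover Use the carryover-adjusted analysis for the
#'   repeated measures designs.
#' @param out_dir Output directory for [run_experiment()].
#' @return A validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment, scenarios = 1:4,
                              designs = .designs,
                              n_grid = default_n_grid(),
                              tau_grid = default_tau_grid(),
                              p_grid = seq(0.1, 1, by = 0.1),
                              n = NULL, tau = 0.25, gamma = 0, p = 0.5,
                              B = 5000, seed = 1L, alpha = 0.05,
                              adjust_carryover = FALSE,
                              out_dir = "nof1sim-results") {
  if (length(experiment) != 1L || !experiment %in% .experiments)
    stop("`experiment` must be one of: ",
         paste(.experiments, collapse = ", "), call. = FALSE)
  if (!all(scenarios %in% 1:4))
    stop("`scenarios` must be a subset of 1:4", call. = FALSE)
  if (!all(designs %in% .designs))
    stop("`designs` must be a subset of nof1/crossover/rct", call. = FALSE)
  .check_grid(n_grid, "n_grid")
  .check_grid(tau_grid, "tau_grid")
  .check_grid(p_grid, "p_grid")
  if (any(p_grid < 0 | p_grid > 1))
    stop("`p_grid` values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0)
    stop("`gamma` must be nonnegative", call. = FALSE)
  if (!is.numeric(B) || B < 1) stop("`B` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (experiment == "random_effects" && (p <= 0 || p >= 1))
    stop("`p` must lie strictly in (0, 1) for random_effects",
         call. = FALSE)
  if (is.null(n)) {
    n <- switch(experiment,
                power_vs_tau = power80_n(scenarios, gamma = gamma),
                random_effects = 100L,
                30L)
  }
  if (!length(n) %in% c(1L, length(scenarios)))
    stop("`n` must have length 1 or one value per scenario", call. = FALSE)
  n <- as.integer(rep_len(n, length(scenarios)))
  structure(list(experiment = experiment,
                 scenarios = as.integer(scenarios), designs = designs,
                 n_grid = n_grid, tau_grid = tau_grid, p_grid = p_grid,
                 n = n, tau = tau, gamma = gamma, p = p,
                 B = as.integer(B), seed = as.integer(seed),
                 alpha = alpha,
                 adjust_carryover = isTRUE(adjust_carryover),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The YAML keys are the arguments of [experiment_config()]; `overrides`
#' (typically parsed CLI flags) take precedence over the file.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(experiment_config, cfg)
}

# full-precision CSV so that operating-characteristic tables round-trip
# exactly through read.csv
.write_csv17 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an operating-characteristic results table
#'
#' @param path CSV written by [run_experiment()] (or [write_oc_csv()]).
#' @return A data frame of operating-characteristic rows.
#' @export
read_oc_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname read_oc_csv
#' @param results A data frame of operating-characteristic rows.
#' @export
write_oc_csv <- function(results, path) .write_csv17(results, path)

#' Run a configured experiment and write its result files
#'
#' Dispatches on `config$experiment`, loops over the configured scenarios
#' and designs, and writes to `config$out_dir`:
#' `results.csv` (one operating-characteristic row per design, scenario
#' and grid point — for `random_effects`, one row per replicate with the
#' BLUP difference), `manifest.json` (the full configuration plus package
#' version), and `log.txt`. Identical configurations and seeds produce
#' byte-identical `results.csv`.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the results data frame and the paths
#'   written.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  say("experiment=%s B=%d seed=%d", config$experiment, config$B,
      config$seed)
  scen_seeds <- .child_seeds(config$seed,
                             length(config$scenarios) *
                               length(config$designs))
  rows <- list(); k <- 0L
  for (si in seq_along(config$scenarios)) {
    s <- config$scenarios[si]
    for (design in config$designs) {
      k <- k + 1L
      if (config$experiment == "random_effects" && design == "rct") next
      mod <- scenario(s, tau = config$tau, carryover = config$gamma)
      res <- switch(
        config$experiment,
        power_vs_n = ,
        carryover = power_curve(mod, design, n_grid = config$n_grid,
                                B = config$B, seed = scen_seeds[k],
                                alpha = config$alpha,
                                adjust_carryover = config$adjust_carryover),
        power_vs_tau = tau_curve(mod, design, tau_grid = config$tau_grid,
                                 n = config$n[si], B = config$B,
                                 seed = scen_seeds[k],
                                 alpha = config$alpha,
                                 adjust_carryover = config$adjust_carryover),
        selection_bias_type1 = selection_bias_oc(
          mod, design, n = config$n[si], p_grid = config$p_grid,
          B = config$B, seed = scen_seeds[k], mode = "type1",
          effect = abs(config$tau), alpha = config$alpha),
        selection_bias_power = selection_bias_oc(
          mod, design, n = config$n[si], p_grid = config$p_grid,
          B = config$B, seed = scen_seeds[k], mode = "power",
          effect = abs(config$tau), alpha = config$alpha),
        random_effects = {
          if (design != "nof1") next  # pair computed once per scenario
          cmp <- compare_random_effects(
            scenario(s, tau = 0, tau_sub = config$tau),
            n = config$n[si], p = config$p, B = config$B,
            seed = scen_seeds[k])
          rbind(
            data.frame(design = "nof1", scenario = s,
                       replicate = seq_along(cmp$nof1$diffs),
                       blup_diff = cmp$nof1$diffs),
            data.frame(design = "crossover", scenario = s,
                       replicate = seq_along(cmp$crossover$diffs),
                       blup_diff = cmp$crossover$diffs))
        })
      rows[[length(rows) + 1L]] <- res
      say("done scenario=%d design=%s (%d rows)", s, design, nrow(res))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  paths <- list(results = file.path(config$out_dir, "results.csv"),
                manifest = file.path(config$out_dir, "manifest.json"),
                log = file.path(config$out_dir, "log.txt"))
  .write_csv17(results, paths$results)
  manifest <- c(unclass(config),
                list(package = "nof1sim",
                     version = as.character(utils::packageVersion("nof1sim"))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)
  say("wrote %s", paths$results)
  invisible(list(results = results, paths = paths))
}

#' Plot power curves from an operating-characteristic table
#'
#' Draws rejection rate against the grid variable (`n`, `tau` or
#' `p_representative`), one line per design, faceted by scenario.
#' Requires ggplot2.
#'
#' @param results Data frame of operating-characteristic rows (from
#'   [power_curve()], [run_experiment()] etc.).
#' @param x Name of the grid column (default guesses the one that
#'   varies).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(results, x = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
  if (is.null(x)) {
    cand <- c("n", "tau", "p_representative")
    vary <- vapply(cand, function(v) length(unique(results[[v]])) > 1L,
                   logical(1))
    x <- if (any(vary)) cand[which(vary)[1L]] else "n"
  }
  gg <- ggplot2::ggplot(results,
                        ggplot2::aes(x = .data[[x]], y = .data[["rejection_rate"]],
                                     colour = .data[["design"]])) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "rejection rate") +
    ggplot2::ylim(0, 1)
  if (length(unique(results$scenario)) > 1L)
    gg <- gg + ggplot2::facet_wrap(~scenario, labeller = ggplot2::label_both)
  gg
}
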