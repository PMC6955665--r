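# prev_treated flag from the treatment sequence, chronologically within
# patient; first period of each patient is 0 by definition
.prev_treated <- function(treatment, patient_id) {
  prev <- c(0L, treatment[-length(treatment)])
  first <- c(TRUE, patient_id[-1L] != patient_id[-length(patient_id)])
  prev[first] <- 0L
  prev
}

.new_trial_data <- function(df, design, seed_info = NULL) {
  structure(df,
            design = design,
            seed_info = seed_info,
            class = c("trial_data", "data.frame"))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> design = %s, %d records, %d patients\n",
              attr(x, "design"), nrow(x), length(unique(x$patient_id))))
  NextMethod()
}

#' Design of a trial dataset
#'
#' @param data A `"trial_data"` object.
#' @return `"nof1"`, `"crossover"` or `"rct"`.
#' @export
trial_design <- function(data) attr(data, "design")

#' Simulate a full aggregated N-of-1 cohort
#'
#' Draws one cohort from the random-intercept model held by `model`:
#' a patient-level intercept \eqn{\mu_i \sim N(\mu, \sigma_\mu^2)} is
#' drawn once per patient, each of the `n_cycles` cycles randomizes which
#' of its two looks receives treatment (probability 1/2, independently per
#' patient-cycle unless `model$resample_order_each_cycle` is `FALSE`), and
#' the outcome of each look is
#' \eqn{\mu_i + \tau_i Z + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma_\epsilon^2)}. When `p_representative < 1` each patient is first
#' labelled `representative` (probability `p`) or `subpopulation`, and
#' \eqn{\tau_i} is `tau` or `tau_sub` accordingly.
#'
#' The carryover increment is *not* applied here: derive the design of
#' interest with [extract_design()] and then call [apply_carryover()], so
#' the increment follows each design's own chronology.
#'
#' @param model A [simulation_model()].
#' @param n Number of patients (at least 2).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return A `"trial_data"` data frame (design `"nof1"`) in chronological
#'   order with columns `patient_id`, `cycle`, `look`, `treatment`,
#'   `outcome`, `prev_treated`, `population`; `2 * n_cycles` rows per
#'   patient.
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario(1), n = 4, seed = 1)
#' head(cohort)
simulate_cohort <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "simulation_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  nc <- model$n_cycles
  per <- 2L * nc

  # draw order: population labels, patient intercepts, per-cycle treatment
  # order, residuals -- keep fixed so that identical seeds give identical
  # cohorts regardless of which design is extracted afterwards
  repr <- if (model$p_representative < 1)
    stats::rbinom(n, 1L, model$p_representative) else rep(1L, n)
  mu_i <- stats::rnorm(n, model$mu, model$sigma_mu)
  if (model$resample_order_each_cycle) {
    treat_first <- stats::rbinom(n * nc, 1L, 0.5)
  } else {
    treat_first <- rep(stats::rbinom(n, 1L, 0.5), each = nc)
  }
  eps <- stats::rnorm(n * per, 0, model$sigma_eps)

  patient_id <- rep.int(seq_len(n), rep.int(per, n))
  cycle <- rep.int(rep.int(seq_len(nc), rep.int(2L, nc)), n)
  look <- rep.int(c(1L, 2L), n * nc)
  treatment <- rep.int(treat_first, rep.int(2L, n * nc))
  second <- look == 2L
  treatment[second] <- 1L - treatment[second]
  tau_pat <- model$tau_sub + (model$tau - model$tau_sub) * repr
  outcome <- mu_i[patient_id] + tau_pat[patient_id] * treatment + eps

  df <- structure(
    list(patient_id = patient_id, cycle = cycle, look = look,
         treatment = treatment, outcome = outcome,
         prev_treated = .prev_treated(treatment, patient_id),
         population = c("subpopulation",
                        "representative")[repr[patient_id] + 1L]),
    class = "data.frame", row.names = c(NA_integer_, -(n * per)))
  .new_trial_data(df, "nof1",
                  seed_info = if (is.null(seed)) "inherited RNG state"
                              else paste0("seed=", seed))
}

#' Derive a design-specific dataset from a simulated N-of-1 cohort
#'
#' All three designs are views of the *same* outcome draws, so design
#' comparisons are not confounded by simulation noise: the crossover trial
#' keeps both cycle-1 looks of every patient; the parallel RCT keeps
#' exactly one cycle-1 look per patient, chosen with equal probability
#' (outcome and treatment assignment together); `"nof1"` returns the
#' cohort unchanged. Outcomes are never re-drawn.
#'
#' @param cohort A full N-of-1 `"trial_data"` cohort, before any carryover
#'   has been applied.
#' @param design `"nof1"`, `"crossover"` or `"rct"`.
#' @param seed Optional integer seed for the RCT's random look selection.
#' @return A `"trial_data"` object for the requested design, with
#'   `prev_treated` recomputed under that design's own chronology (all 0
#'   for the single-period RCT).
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario(1), n = 30, seed = 1)
#' nrow(extract_design(cohort, "crossover"))  # 60
#' nrow(extract_design(cohort, "rct"))        # 30
extract_design <- function(cohort, design = c("nof1", "crossover", "rct"),
                           seed = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(cohort, "trial_data"))
  if (!identical(attr(cohort, "design"), "nof1"))
    stop("`cohort` must be a full N-of-1 cohort", call. = FALSE)
  if (isTRUE(attr(cohort, "carryover")) || !is.null(attr(cohort, "carryover")))
    stop("extract designs before applying carryover", call. = FALSE)
  if (design == "nof1") return(cohort)
  if (!is.null(seed)) set.seed(seed)
  keep <- cohort$cycle == 1L
  out <- cohort[keep, , drop = FALSE]
  if (design == "rct") {
    ids <- unique(out$patient_id)
    pick_look <- stats::rbinom(length(ids), 1L, 0.5) + 1L
    out <- out[out$look == pick_look[match(out$patient_id, ids)], ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out$prev_treated <- .prev_treated(out$treatment, out$patient_id)
  .new_trial_data(out, design, seed_info = attr(cohort, "seed_info"))
}

#' Add a carryover increment following treated periods
#'
#' Adds `gamma` to every outcome whose chronologically preceding period,
#' *within the dataset's own design*, was a treatment period. For the
#' aggregated N-of-1 design carryover therefore acts both within a cycle
#' (placebo look directly after the treatment look) and across the cycle
#' boundary (first look of a cycle after a treatment look ending the
#' previous cycle). For the crossover design only treatment-first patients
#' are affected (their placebo look is increased). The parallel RCT has a
#' single period per patient and is returned unchanged. The increment does
#' not compound: a period is raised by exactly `gamma` when its immediate
#' predecessor was treated, regardless of earlier history.
#'
#' @param data A `"trial_data"` object whose rows are in chronological
#'   order within patient (as produced by [simulate_cohort()] /
#'   [extract_design()]).
#' @param gamma Nonnegative carryover increment \eqn{\gamma}.
#' @return `data` with `outcome` incremented where `prev_treated == 1`,
#'   `prev_treated` recomputed, and attribute `carryover = gamma` set.
#' @export
apply_carryover <- function(data, gamma) {
  stopifnot(inherits(data, "trial_data"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0)
    stop("`gamma` must be a nonnegative number", call. = FALSE)
  if (!is.null(attr(data, "carryover")))
    stop("carryover has already been applied to this dataset", call. = FALSE)
  design <- attr(data, "design")
  if (design != "rct" && gamma > 0) {
    data$prev_treated <- .prev_treated(data$treatment, data$patient_id)
    data$outcome <- data$outcome + gamma * data$prev_treated
  }
  attr(data, "carryover") <- gamma
  data
}

#' Read or write a trial dataset as tidy CSV
#'
#' One row per observation period with the columns `patient_id`, `cycle`,
#' `look`, `treatment`, `outcome`, `prev_treated`, `population`; UTF-8,
#' one header row. Full double precision is preserved on round trip.
#'
#' @param data A `"trial_data"` object.
#' @param path File path.
#' @param design Design label to attach on reading (`write_trial_csv`
#'   stores it in a `# design:` comment line which `read_trial_csv` picks
#'   up automatically when `design` is `NULL`).
#' @return `read_trial_csv` returns a `"trial_data"` object;
#'   `write_trial_csv` returns `path` invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# design: ", attr(data, "design")), con)
  df <- as.data.frame(data)
  df$outcome <- sprintf("%.17g", df$outcome)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path, design = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(design)) {
    if (!grepl("^# design: ", first))
      stop("no `# design:` header; pass `design` explicitly", call. = FALSE)
    design <- sub("^# design: ", "", first)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("patient_id", "cycle", "look", "treatment", "outcome",
            "prev_treated", "population")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  .new_trial_data(df[need], match.arg(design, c("nof1", "crossover", "rct")),
                  seed_info = paste0("file=", path))
}
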