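#' Per-patient uniform draw streams
#'
#' One uniform per patient per purpose (triage decision, secondary
#' transfer, 30-day death, 30-day-to-1-year death, long-term survival
#' inversion). The same streams are shared by all triage tools within a
#' run, so tools differ only through their decision thresholds (common
#' random numbers). Uses the current RNG state.
#'
#' @param n Number of patients.
#' @return Named list of five uniform vectors.
#' @export
make_draws <- function(n) {
  list(u_triage = stats::runif(n), u_transfer = stats::runif(n),
       u_30d = stats::runif(n), u_1yr = stats::runif(n),
       u_long = stats::runif(n))
}

#' Simulate all triage strategies on one cohort with one parameter set
#'
#' Core of the microsimulation. The long-term death age, survivor QALY
#' stream and survivor long-term cost stream do not depend on the care
#' pathway (the long-term hazard ratio and utility multiplier depend only
#' on ISS), so they are computed once per parameter set and reused across
#' all tools; per tool only the triage tree, 30-day and 1-year stages are
#' re-evaluated.
#'
#' @param cohort Patient data frame (`age`, `male`, `iss`, `gcs`, `blunt`).
#' @param params A `trauma_params` (point estimates or a PSA draw).
#' @param life_table Life table data frame.
#' @param cost_schedule NHS cost schedule data frame.
#' @param draws Output of [make_draws()] for `nrow(cohort)` patients.
#' @return Data frame of per-strategy outcomes, one row per tool:
#'   MTC flows per 100,000 (total and by severity stratum), proportions of
#'   patients ever at an MTC by stratum (`p_mtc_iss16`, `p_mtc_iss9to15`,
#'   used by the tariff re-costing shortcut), death proportions, mean life
#'   years, mean discounted QALYs and mean discounted costs.
#' @export
simulate_strategies <- function(cohort, params, life_table, cost_schedule,
                                draws) {
  stopifnot(nrow(cohort) >= 1, length(draws$u_triage) == nrow(cohort))
  validate_cohort(cohort)
  cl <- params$clinical
  rate <- params$economics$discount_rate
  iss16 <- cohort$iss >= 16
  iss9to15 <- cohort$iss >= 9 & cohort$iss < 16

  ps <- p_survival_30d(cohort, params$survival_model)
  hr <- ifelse(iss16, cl$hr_longterm_iss16, cl$hr_longterm_issLT16)
  death_age <- simulate_death_age(cohort$age, cohort$male, hr, life_table,
                                  draws$u_long)
  dq <- discounted_qalys(cohort$age, death_age, cohort$male, cohort$iss,
                         rate, params$utility)
  lt_cost <- longterm_discounted_cost(cohort$age, death_age, cohort$male,
                                      iss16, rate, cost_schedule, params$cost)
  u0 <- patient_utility(cohort$age, cohort$male, cohort$iss, params$utility)

  rows <- lapply(seq_len(nrow(params$tools)), function(k) {
    tool <- params$tools[k, ]
    pos <- classify_triage(iss16, tool$sensitivity, tool$specificity,
                           draws$u_triage)
    pw <- assign_pathway(pos, iss16, cl$transfer, draws$u_transfer)
    d30 <- p_death_30d(cohort, pw$ever_mtc, cl, params$survival_model, ps = ps)
    died30 <- draws$u_30d < d30
    p1 <- p_death_30d_to_1yr(cohort$iss, pw$ever_mtc, cl)
    died1yr <- !died30 & draws$u_1yr < p1
    surv1yr <- !died30 & !died1yr

    life_years <- ifelse(died30, 15 / 365.25,
                         ifelse(died1yr, 0.5, dq$life_years))
    qalys <- ifelse(died30, 0, ifelse(died1yr, 0.5 * u0, dq$qalys))
    costs <- acute_cost(cohort, pw, params$cost) +
      post_discharge_cost(!died30, params$cost) +
      ifelse(surv1yr, lt_cost, 0)

    data.frame(
      tool = tool$label,
      sensitivity = tool$sensitivity,
      specificity = tool$specificity,
      mtc_per_100k = mean(pw$ever_mtc) * 1e5,
      mtc_iss16_per_100k = mean(pw$ever_mtc & iss16) * 1e5,
      mtc_issLT16_per_100k = mean(pw$ever_mtc & !iss16) * 1e5,
      p_mtc_iss16 = mean(pw$ever_mtc & iss16),
      p_mtc_iss9to15 = mean(pw$ever_mtc & iss9to15),
      p_died_30d = mean(died30),
      p_died_30d_1yr = mean(died1yr),
      mean_life_years = mean(life_years),
      mean_qalys_disc = mean(qalys),
      mean_costs_disc = mean(costs),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Deterministic base-case analysis
#'
#' Runs every triage tool on the cohort with all parameters at their point
#' estimates, under common random numbers.
#'
#' @param cohort Patient data frame.
#' @param params A `trauma_params`.
#' @param life_table,cost_schedule Optional; synthetic defaults are
#'   generated at the parameter set's horizon age cap.
#' @param seed Integer seed for the patient event draws.
#' @return Per-strategy outcome data frame (see [simulate_strategies()]).
#' @export
run_deterministic <- function(cohort, params = default_parameters(),
                              life_table = NULL, cost_schedule = NULL,
                              seed = 1L) {
  cap <- params$economics$horizon_age_cap
  if (is.null(life_table)) life_table <- make_life_table(cap)
  if (is.null(cost_schedule)) cost_schedule <- make_nhs_cost_schedule(cap)
  set.seed(seed)
  draws <- make_draws(nrow(cohort))
  simulate_strategies(cohort, params, life_table, cost_schedule, draws)
}

#' Probabilistic sensitivity analysis
#'
#' Fixes one synthetic cohort per seed, then for each run draws one
#' parameter set from the PSA distributions and simulates all tools with
#' fresh patient-event uniforms (shared across tools within the run).
#' Per-strategy PSA means are the arithmetic averages of the per-run
#' outcomes; decision statistics (ICERs, frontier) should be computed from
#' those mean costs and mean QALYs via [incremental_analysis()].
#'
#' Run `r` uses seed `seed + r - 1`, so a single run is reproducible in
#' isolation with [run_deterministic()] given the same drawn parameters.
#'
#' @param cohort A cohort data frame, or a [cohort_spec()] from which
#'   `n_patients` are sampled at `seed`.
#' @param params A `trauma_params`.
#' @param n_runs Number of PSA runs (the full-scale analysis uses 2000).
#' @param n_patients Number of simulated patients per run (full scale:
#'   25,000). Ignored when `cohort` is a data frame.
#' @param seed Integer master seed.
#' @param dists PSA distribution specs; defaults to
#'   [psa_distributions()] of `params`.
#' @param life_table,cost_schedule Optional; synthetic defaults otherwise.
#' @return A `trauma_psa` object: list with `runs` (per-run per-strategy
#'   outcomes), `means` (per-strategy means over runs), `n_runs`,
#'   `n_patients`, `seed`.
#' @export
run_psa <- function(cohort, params = default_parameters(), n_runs = 100L,
                    n_patients = 2000L, seed = 1L,
                    dists = psa_distributions(params),
                    life_table = NULL, cost_schedule = NULL) {
  stopifnot(n_runs >= 1)
  cap <- params$economics$horizon_age_cap
  if (is.null(life_table)) life_table <- make_life_table(cap)
  if (is.null(cost_schedule)) cost_schedule <- make_nhs_cost_schedule(cap)
  if (inherits(cohort, "cohort_spec")) {
    cohort <- sample_cohort(n_patients, cohort, seed = seed)
  }
  n_patients <- nrow(cohort)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed((seed + r - 1L) %% .Machine$integer.max)
    drawn <- draw_parameters(params, dists)
    draws <- make_draws(n_patients)
    out <- simulate_strategies(cohort, drawn, life_table, cost_schedule, draws)
    out$run <- r
    runs[[r]] <- out
  }
  runs <- do.call(rbind, runs)
  num_cols <- setdiff(names(runs)[vapply(runs, is.numeric, logical(1))], "run")
  means <- stats::aggregate(runs[num_cols], by = list(tool = runs$tool), mean)
  means <- means[match(params$tools$label, means$tool), , drop = FALSE]
  rownames(means) <- NULL
  structure(list(runs = runs, means = means, n_runs = n_runs,
                 n_patients = n_patients, seed = seed),
            class = "trauma_psa")
}

#' @export
print.trauma_psa <- function(x, ...) {
  cat("<trauma_psa> ", x$n_runs, " runs x ", x$n_patients, " patients, seed ",
      x$seed, "\n", sep = "")
  print(x$means[, c("tool", "mtc_per_100k", "mean_qalys_disc",
                    "mean_costs_disc")])
  invisible(x)
}

#' Running-mean stability check for PSA outcomes
#'
#' Tracks the running mean of a per-run outcome and flags convergence when
#' no point in the trailing window (last 10% of runs by default) deviates
#' from the final mean by more than `tol` (relative to the final mean's
#' magnitude, or absolute when that magnitude is below 1).
#'
#' @param psa A `trauma_psa`, or a numeric vector of per-run values.
#' @param outcome Outcome column name (when `psa` is a `trauma_psa`).
#' @param tool Tool label; defaults to the first tool.
#' @param tol Stability tolerance (default 0.005).
#' @param window Trailing fraction of runs examined (default 0.1).
#' @return List with `trace` (running means), `converged`, `final`.
#' @export
stability_check <- function(psa, outcome = "mean_qalys_disc", tool = NULL,
                            tol = 0.005, window = 0.1) {
  values <- if (is.numeric(psa)) {
    psa
  } else {
    runs <- psa$runs
    if (is.null(tool)) tool <- runs$tool[1]
    runs[runs$tool == tool, outcome]
  }
  if (length(values) < 2) stop("need at least 2 runs", call. = FALSE)
  trace <- cumsum(values) / seq_along(values)
  final <- trace[length(trace)]
  win <- seq.int(max(1L, ceiling(length(trace) * (1 - window))), length(trace))
  converged <- max(abs(trace[win] - final)) < tol * max(1, abs(final))
  list(trace = trace, converged = converged, final = final)
}
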