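#' Full incremental cost-effectiveness analysis
#'
#' Orders strategies by effectiveness (QALYs), removes dominated
#' strategies (another strategy has at least the QALYs at no more cost,
#' with one comparison strict; exact ties are broken by lower cost, then
#' input order) and extendedly dominated strategies (those above the lower
#' convex hull of the cost--QALY cloud, i.e. whose incremental ICER
#' sequence would not be strictly increasing), then computes the ICER of
#' each remaining strategy against the previous frontier member. The least
#' effective frontier member is the comparator and has no ICER.
#'
#' @param outcomes Data frame with columns `tool` (label), a QALY column
#'   and a cost column.
#' @param qaly_col,cost_col Column names (defaults `mean_qalys_disc`,
#'   `mean_costs_disc`; plain `qalys`/`costs` also recognised).
#' @return A `cea_frontier` data frame: `tool`, `qalys`, `costs`, `status`
#'   (`"comparator"`, `"frontier"`, `"dominated"`, `"extendedly dominated"`)
#'   and `icer` (GBP/QALY; `NA` off the frontier and for the comparator),
#'   ordered by increasing QALYs.
#' @export
#' @examples
#' x <- data.frame(tool = c("A", "C", "B"),
#'                 qalys = c(10, 10.5, 11), costs = c(100, 190, 200))
#' incremental_analysis(x)
incremental_analysis <- function(outcomes,
                                 qaly_col = NULL, cost_col = NULL) {
  if (is.null(qaly_col)) {
    qaly_col <- intersect(c("mean_qalys_disc", "qalys"), names(outcomes))[1]
  }
  if (is.null(cost_col)) {
    cost_col <- intersect(c("mean_costs_disc", "costs"), names(outcomes))[1]
  }
  if (is.na(qaly_col) || is.na(cost_col)) {
    stop("outcomes must contain QALY and cost columns", call. = FALSE)
  }
  q <- outcomes[[qaly_col]]; c_ <- outcomes[[cost_col]]
  if (any(!is.finite(q)) || any(!is.finite(c_))) {
    stop("QALYs and costs must be finite", call. = FALSE)
  }
  n <- length(q)
  res <- data.frame(tool = as.character(outcomes$tool), qalys = q, costs = c_,
                    status = NA_character_, icer = NA_real_,
                    stringsAsFactors = FALSE)
  ord <- order(res$qalys, res$costs, seq_len(n))
  res <- res[ord, , drop = FALSE]

  dominated <- vapply(seq_len(n), function(i) {
    better <- res$qalys >= res$qalys[i] & res$costs <= res$costs[i] &
      (res$qalys > res$qalys[i] | res$costs < res$costs[i])
    tie <- res$qalys == res$qalys[i] & res$costs == res$costs[i]
    any(better) || any(tie & seq_len(n) < i)  # exact-tie: keep first
  }, logical(1))
  res$status[dominated] <- "dominated"

  cand <- which(!dominated)  # QALYs and costs strictly increasing along cand
  repeat {
    if (length(cand) <= 2) break
    icers <- diff(res$costs[cand]) / diff(res$qalys[cand])
    drop <- which(diff(icers) <= 0)  # frontier ICERs must strictly increase
    if (!length(drop)) break
    cand <- cand[-(drop[1] + 1L)]
  }
  ext <- setdiff(which(!dominated), cand)
  res$status[ext] <- "extendedly dominated"
  res$status[cand] <- "frontier"
  res$status[cand[1]] <- "comparator"
  if (length(cand) > 1) {
    res$icer[cand[-1]] <- diff(res$costs[cand]) / diff(res$qalys[cand])
  }
  class(res) <- c("cea_frontier", "data.frame")
  res
}

#' Cost-effective strategy at a given MAICER
#'
#' The most effective frontier strategy whose ICER does not exceed the
#' maximum acceptable ICER (boundary inclusive); the comparator when none
#' qualifies. Equivalent to maximising net monetary benefit
#' `maicer * QALYs - costs` over all strategies.
#'
#' @param frontier A `cea_frontier` from [incremental_analysis()].
#' @param maicer Maximum acceptable ICER in GBP per QALY (> 0).
#' @return The selected strategy's label.
#' @export
cost_effective_at <- function(frontier, maicer) {
  stopifnot(inherits(frontier, "cea_frontier"), maicer > 0)
  on_f <- which(frontier$status %in% c("comparator", "frontier"))
  ok <- on_f[is.na(frontier$icer[on_f]) | frontier$icer[on_f] <= maicer]
  # frontier ICERs increase, so qualifying members are a prefix; take the last
  frontier$tool[max(ok)]
}

#' @export
print.cea_frontier <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Scenario: partial MTC benefit for patients with ISS 9--15
#'
#' Returns a parameter set in which local-only patients with ISS 9--15
#' receive the stated fraction of the MTC benefit observed for ISS >= 16,
#' by linear interpolation on the relative-risk scale
#' ([interpolated_rr()]): the 30-day RR interpolates from 1.25 and the
#' 30-day-to-1-year RR from 1.64. Patients with ISS < 9 are unaffected.
#'
#' @param params A `trauma_params`.
#' @param fraction Benefit fraction in \[0, 1\] (the scenario grid uses
#'   0, 0.25, 0.5, 0.75).
#' @return A modified `trauma_params`.
#' @export
#' @examples
#' p <- scenario_iss9to15_benefit(default_parameters(), 0.5)
#' p$clinical$rr_1yr_local_iss9to15  # 1.32
scenario_iss9to15_benefit <- function(params, fraction) {
  params$clinical$rr_death30_local_iss9to15 <-
    interpolated_rr(params$clinical$rr_death30_local_iss16, fraction)
  params$clinical$rr_1yr_local_iss9to15 <-
    interpolated_rr(params$clinical$rr_1yr_local_iss16, fraction)
  params
}

#' Threshold analysis over MTC admission tariffs
#'
#' Re-evaluates the cost-effective tool over a grid of MTC best practice
#' tariffs. Tariffs enter the cost ledger linearly (a patient pays the
#' ISS-stratum tariff once if ever at an MTC) and do not affect survival,
#' so per-strategy mean costs are re-priced exactly from the recorded MTC
#' proportions without re-simulating:
#' `cost' = cost + (t16 - t16_base) * p_mtc_iss16 +
#'          (t915 - t915_base) * p_mtc_iss9to15`.
#'
#' @param outcomes Per-strategy outcomes (PSA means or deterministic
#'   results) containing `p_mtc_iss16`, `p_mtc_iss9to15`,
#'   `mean_costs_disc`, `mean_qalys_disc`.
#' @param params The `trauma_params` the outcomes were produced with
#'   (supplies the base tariffs).
#' @param iss16_tariffs,iss9to15_tariffs Tariff grids in GBP (>= 0).
#' @param maicers MAICER grid (defaults to the parameter set's).
#' @return Data frame with one row per (tariff pair, MAICER):
#'   `iss16_tariff`, `iss9to15_tariff`, `maicer`, `tool`.
#' @export
tariff_threshold_grid <- function(outcomes, params,
                                  iss16_tariffs, iss9to15_tariffs,
                                  maicers = params$economics$maicers) {
  stopifnot(length(iss16_tariffs) >= 1, length(iss9to15_tariffs) >= 1)
  if (any(iss16_tariffs < 0) || any(iss9to15_tariffs < 0)) {
    stop("tariffs must be non-negative", call. = FALSE)
  }
  base16 <- params$cost$mtc_admit_iss16
  base915 <- params$cost$mtc_admit_iss9to15
  grid <- expand.grid(iss16_tariff = iss16_tariffs,
                      iss9to15_tariff = iss9to15_tariffs,
                      maicer = maicers, KEEP.OUT.ATTRS = FALSE)
  grid$tool <- vapply(seq_len(nrow(grid)), function(i) {
    oc <- outcomes
    oc$mean_costs_disc <- oc$mean_costs_disc +
      (grid$iss16_tariff[i] - base16) * oc$p_mtc_iss16 +
      (grid$iss9to15_tariff[i] - base915) * oc$p_mtc_iss9to15
    cost_effective_at(incremental_analysis(oc), grid$maicer[i])
  }, character(1))
  grid
}
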