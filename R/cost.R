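#' Acute (admission) cost
#'
#' Sum of: the MTC admission best practice tariff if the patient ever
#' received MTC care (ISS >= 16: 2819; 9 <= ISS < 16: 1466; ISS < 9: no
#' tariff row, hence 0); the secondary transfer cost (252) if a local to
#' MTC transfer occurred; and the treatment cost from the blunt or
#' penetrating ISS band table. Band edges are half-open `(lo, hi]`,
#' following the tariff tables literally (note the blunt/penetrating
#' boundary asymmetry: blunt bands split at ISS 16, penetrating at 15).
#'
#' @param patients Data frame with `iss`, `blunt`.
#' @param pathway Data frame from [assign_pathway()].
#' @param cost `cost` section of a `trauma_params`.
#' @return Cost in GBP per patient.
#' @export
acute_cost <- function(patients, pathway, cost) {
  premium <- ifelse(pathway$ever_mtc,
                    ifelse(patients$iss >= 16, cost$mtc_admit_iss16,
                           ifelse(patients$iss >= 9, cost$mtc_admit_iss9to15, 0)),
                    0)
  transfer <- ifelse(pathway$transferred, cost$transfer_cost, 0)
  premium + transfer + treatment_cost(patients$iss, patients$blunt, cost)
}

#' Treatment cost by ISS band and trauma type
#'
#' @param iss ISS vector (1--75).
#' @param blunt 0/1 vector.
#' @param cost `cost` section of a `trauma_params`.
#' @export
treatment_cost <- function(iss, blunt, cost) {
  lookup <- function(tab, x) {
    i <- findInterval(x, tab$lo, left.open = TRUE)  # (lo, hi] bands
    i[i == 0L] <- 1L
    bad <- x > tab$hi[nrow(tab)] | x < 0
    if (any(bad)) stop("ISS outside treatment band coverage", call. = FALSE)
    tab$cost[i]
  }
  out <- numeric(length(iss))
  b <- blunt > 0
  if (any(b)) out[b] <- lookup(cost$blunt_treatment_bands, iss[b])
  if (any(!b)) out[!b] <- lookup(cost$penetrating_treatment_bands, iss[!b])
  out
}

#' Post-discharge cost (discharge to 6 months)
#'
#' A single charge of `post_discharge_6mo` (1766) to every 30-day survivor;
#' 30-day decedents accrue nothing beyond the acute ledger.
#'
#' @param survived_30d Logical vector.
#' @param cost `cost` section of a `trauma_params`.
#' @export
post_discharge_cost <- function(survived_30d, cost) {
  ifelse(survived_30d, cost$post_discharge_6mo, 0)
}

#' Generate a stylised NHS annual cost schedule
#'
#' Synthetic age/sex schedule of annual general-population NHS costs
#' (GBP), shaped like published English per-capita spending curves: higher
#' in infancy, flat through adulthood, rising steeply from late middle
#' age. A stand-in for person-level costing data, not a copy of any
#' published schedule.
#'
#' @param cap Maximum age covered.
#' @return Data frame `age_lo`, `age_hi`, `sex`, `annual_cost` with
#'   contiguous `[age_lo, age_hi]` bands.
#' @export
make_nhs_cost_schedule <- function(cap = 100) {
  lo <- c(0, 5, 15, 30, 40, 50, 60, 70, 80, 90)
  hi <- c(4, 14, 29, 39, 49, 59, 69, 79, 89, cap)
  base <- c(1200, 700, 650, 800, 1000, 1350, 1900, 2900, 4200, 5600)
  rbind(
    data.frame(age_lo = lo, age_hi = hi, sex = "male", annual_cost = base * 0.95),
    data.frame(age_lo = lo, age_hi = hi, sex = "female", annual_cost = base * 1.05)
  )
}

#' @rdname make_nhs_cost_schedule
#' @param schedule Schedule data frame.
#' @param path CSV path (`age_lo,age_hi,sex,annual_cost`).
#' @export
write_nhs_cost_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname make_nhs_cost_schedule
#' @export
read_nhs_cost_schedule <- function(path) {
  s <- utils::read.csv(path)
  need <- c("age_lo", "age_hi", "sex", "annual_cost")
  if (!all(need %in% names(s))) {
    stop("cost schedule must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (any(s$annual_cost < 0)) stop("negative annual cost", call. = FALSE)
  s
}

# per-age lookup matrix (rows: age 0..cap, cols male/female)
cost_schedule_matrix <- function(schedule) {
  cap <- max(schedule$age_hi)
  m <- matrix(NA_real_, nrow = cap + 1L, ncol = 2L,
              dimnames = list(NULL, c("male", "female")))
  for (s in c("male", "female")) {
    sub <- schedule[schedule$sex == s, ]
    for (i in seq_len(nrow(sub))) {
      m[(sub$age_lo[i]:sub$age_hi[i]) + 1L, s] <- sub$annual_cost[i]
    }
  }
  if (anyNA(m)) stop("cost schedule does not cover all ages to the cap for both sexes",
                     call. = FALSE)
  m
}

#' Long-term annual NHS cost for a trauma survivor
#'
#' The age/sex general-population annual cost scaled by the lifetime
#' multiplier: 1.45 for ISS >= 16, 1.25 for all other suspected major
#' trauma survivors (the sources group all ISS < 16 together, including
#' ISS < 9).
#'
#' @param age Integer age(s) within the schedule.
#' @param male 0/1 vector.
#' @param iss_ge16 Logical vector.
#' @param schedule NHS cost schedule data frame.
#' @param cost `cost` section of a `trauma_params`.
#' @export
longterm_annual_cost <- function(age, male, iss_ge16, schedule, cost) {
  m <- cost_schedule_matrix(schedule)
  if (any(age < 0 | age > nrow(m) - 1L)) {
    stop("age beyond cost schedule cap", call. = FALSE)
  }
  base <- ifelse(male > 0, m[age + 1L, "male"], m[age + 1L, "female"])
  base * ifelse(iss_ge16, cost$longterm_mult_iss16, cost$longterm_mult_issLT16)
}

#' Lifetime cost ledger for one set of patients
#'
#' Year 0 (undiscounted): acute cost (treatment + MTC tariff + transfer)
#' plus the post-discharge charge for 30-day survivors. Years 1 to death:
#' discounted long-term annual costs with a half-year in the year of
#' death; patients dying within the first year accrue no long-term costs.
#'
#' @param patients Data frame (`age`, `male`, `iss`, `blunt`).
#' @param pathway Data frame from [assign_pathway()].
#' @param died_30d,died_30d_to_1yr Logical vectors.
#' @param death_age Death age for 1-year survivors (ignored for others).
#' @param rate Annual discount rate.
#' @param schedule NHS cost schedule.
#' @param cost `cost` section of a `trauma_params`.
#' @return Data frame ledger: `acute`, `transfer`, `post_discharge`,
#'   `longterm_discounted`, `total_discounted` (GBP; `acute` excludes the
#'   transfer component, which is reported separately).
#' @export
lifetime_costs <- function(patients, pathway, died_30d, died_30d_to_1yr,
                           death_age, rate, schedule, cost) {
  transfer <- ifelse(pathway$transferred, cost$transfer_cost, 0)
  acute <- acute_cost(patients, pathway, cost) - transfer
  post <- post_discharge_cost(!died_30d, cost)
  survived_1yr <- !died_30d & !died_30d_to_1yr
  lt <- numeric(nrow(patients))
  if (any(survived_1yr)) {
    idx <- which(survived_1yr)
    lt[idx] <- longterm_discounted_cost(
      patients$age[idx], death_age[idx], patients$male[idx],
      patients$iss[idx] >= 16, rate, schedule, cost)
  }
  data.frame(acute = acute, transfer = transfer, post_discharge = post,
             longterm_discounted = lt,
             total_discounted = acute + transfer + post + lt)
}

#' Discounted long-term cost stream
#'
#' Sum over cycles `t = 1, 2, ...` of the long-term annual cost at age
#' `start_age + t`, discounted at `rate`, with a half-year credit in the
#' year of death (mid-cycle convention).
#'
#' @inheritParams longterm_annual_cost
#' @param start_age Age at injury.
#' @param death_age Age at death.
#' @param rate Annual discount rate.
#' @export
longterm_discounted_cost <- function(start_age, death_age, male, iss_ge16,
                                     rate, schedule, cost) {
  m <- cost_schedule_matrix(schedule)
  cap <- nrow(m) - 1L
  male <- rep_len(male, length(death_age))
  iss_ge16 <- rep_len(iss_ge16, length(death_age))
  mult <- ifelse(iss_ge16, cost$longterm_mult_iss16, cost$longterm_mult_issLT16)
  L <- death_age - start_age
  annual_accrual(start_age, L, rate, from = 1L,
                 value_at = function(idx, ages) {
                   a <- pmin(floor(ages), cap)
                   base <- ifelse(male[idx] > 0, m[a + 1L, "male"],
                                  m[a + 1L, "female"])
                   base * mult[idx]
                 })
}
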