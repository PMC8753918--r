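#' General-population utility
#'
#' Quadratic age/sex EQ-5D regression for the UK general population:
#' `u = c + b_age*age + b_age2*age^2 + b_male*male`, clipped to \[0, 1\].
#' `male` may be a 0/1 indicator or a population proportion (e.g. 0.591 to
#' reproduce the utility-study reference population).
#'
#' @param age Age in years (vector).
#' @param male 0/1, logical, or a proportion in \[0, 1\].
#' @param utility `utility` section of a `trauma_params`.
#' @return Utilities in \[0, 1\].
#' @export
#' @examples
#' u <- default_parameters()$utility
#' round(gen_pop_utility(61, 0.591, u), 3)  # 0.824
gen_pop_utility <- function(age, male, utility) {
  stopifnot(all(age >= 0))
  v <- utility$ara_constant + utility$ara_age * age +
    utility$ara_age2 * age^2 + utility$ara_male * as.numeric(male)
  pmin(1, pmax(0, v))
}

#' Utility multiplier relative to the general population
#'
#' The post-injury utility of a patient group divided by the age/sex
#' matched general-population utility; applied multiplicatively to each
#' simulated patient's own general-population utility.
#'
#' @param u_group Observed group utility (e.g. 0.65 one year post-injury).
#' @param u_ref Matched general-population utility (> 0).
#' @export
#' @examples
#' utility_multiplier(0.65, 0.824)  # ~0.789
utility_multiplier <- function(u_group, u_ref) {
  if (any(u_ref <= 0)) stop("reference utility must be > 0", call. = FALSE)
  u_group / u_ref
}

# multiplier for ISS >= 9 implied by the parameter set: u_iss9plus over the
# general-population utility of the utility-study reference population
injury_multiplier <- function(utility) {
  ref <- gen_pop_utility(utility$ref_age, utility$ref_male_prop, utility)
  utility_multiplier(utility$u_iss9plus, ref)
}

#' Patient utility given injury history
#'
#' General-population utility at the patient's current age and sex, scaled
#' by the injury multiplier for patients with ISS >= 9; injuries with
#' ISS < 9 are assumed to have no long-term effect on utility.
#'
#' @inheritParams gen_pop_utility
#' @param iss ISS vector.
#' @export
patient_utility <- function(age, male, iss, utility) {
  mult <- ifelse(iss >= 9, injury_multiplier(utility), 1)
  pmin(1, gen_pop_utility(age, male, utility) * mult)
}

#' Discounted lifetime QALYs
#'
#' Accrues utility in annual cycles from the year of injury (`t = 0`,
#' undiscounted) to death. Each whole year lived contributes
#' `patient_utility(age + t) / (1 + rate)^t`; the year of death contributes
#' the fraction of the year lived (one half under the mid-cycle death
#' convention). Vectorised over patients.
#'
#' @param start_age Age at injury.
#' @param death_age Age at death (>= `start_age`).
#' @param male,iss Patient covariates.
#' @param rate Annual discount rate (>= 0); 0.035 in the base case.
#' @param utility `utility` section of a `trauma_params`.
#' @return List with numeric vectors `qalys` (discounted) and
#'   `life_years` (undiscounted, `death_age - start_age`).
#' @export
discounted_qalys <- function(start_age, death_age, male, iss, rate, utility) {
  if (any(death_age < start_age)) {
    stop("death age before start age", call. = FALSE)
  }
  L <- death_age - start_age
  male <- rep_len(male, length(L))
  iss <- rep_len(iss, length(L))
  q <- annual_accrual(start_age, L, rate, from = 0L,
                      value_at = function(idx, ages) {
                        patient_utility(ages, male[idx], iss[idx], utility)
                      })
  list(qalys = q, life_years = L)
}

# Shared discounted annual accrual: sum over cycles t = from, from+1, ...
# of value_at(idx, start_age + t) * min(1, L - t) / (1 + rate)^t, where idx
# are the indices of patients still alive at cycle t.
annual_accrual <- function(start_age, L, rate, from, value_at) {
  n <- length(L)
  start_age <- rep_len(start_age, n)
  total <- numeric(n)
  if (all(L <= from)) return(total)
  t_max <- ceiling(max(L)) - 1L
  for (t in seq(from, max(from, t_max))) {
    idx <- which(L > t)
    if (!length(idx)) break
    credit <- pmin(1, L[idx] - t)
    v <- value_at(idx, start_age[idx] + t)
    total[idx] <- total[idx] + credit * v / (1 + rate)^t
  }
  total
}
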