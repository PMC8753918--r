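#' 30-day probability of survival
#'
#' Logistic survival equation in the style of the Trauma Audit and Research
#' Network (TARN) probability-of-survival models:
#' `logit(Ps) = b0 + b_age*age + b_iss*ISS + b_gcs*GCS + b_male*male`.
#' The default coefficients shipped with the package are illustrative,
#' TARN-like values calibrated so that cohort-level 30-day mortality is a
#' plausible ~4%; replace them via the parameter file for a calibrated
#' analysis. The model form is pluggable in principle but only
#' `logit_linear` ships.
#'
#' @param patients Data frame with columns `age`, `iss`, `gcs`, `male`.
#' @param model A `survival_model` list (`form`, `coefficients`) as stored
#'   in a `trauma_params`.
#' @return Vector of survival probabilities in (0, 1).
#' @export
p_survival_30d <- function(patients, model) {
  if (!identical(model$form, "logit_linear")) {
    stop("unsupported survival model form: ", model$form, call. = FALSE)
  }
  b <- model$coefficients
  need <- c("intercept", "age", "iss", "gcs", "male")
  if (!all(need %in% names(b))) {
    stop("missing coefficient(s): ",
         paste(setdiff(need, names(b)), collapse = ", "), call. = FALSE)
  }
  lp <- b[["intercept"]] + b[["age"]] * patients$age + b[["iss"]] * patients$iss +
    b[["gcs"]] * patients$gcs + b[["male"]] * patients$male
  stats::plogis(lp)
}

#' 30-day probability of death with the MTC effect applied
#'
#' Converts survival to death (`1 - Ps`) and applies the local-hospital
#' relative risk: patients with ISS >= 16 treated only at a local hospital
#' have their 30-day death probability multiplied by
#' `rr_death30_local_iss16` (1.25); patients with ISS 9--15 by the scenario
#' lever `rr_death30_local_iss9to15` (1 in the base case); ISS < 9 by
#' `rr_death30_local_issLT16` (1, an assumption). Probabilities are capped
#' at 1.
#'
#' @param patients Data frame with `age`, `iss`, `gcs`, `male`.
#' @param ever_mtc Logical vector: patient received MTC care.
#' @param clinical `clinical` section of a `trauma_params`.
#' @param model Survival model specification.
#' @param ps Optional precomputed [p_survival_30d()] values.
#' @return Vector of death probabilities in \[0, 1\].
#' @export
p_death_30d <- function(patients, ever_mtc, clinical, model,
                        ps = p_survival_30d(patients, model)) {
  d <- 1 - ps
  rr <- rep(1, length(d))
  local <- !ever_mtc
  rr[local & patients$iss >= 16] <- clinical$rr_death30_local_iss16
  rr[local & patients$iss >= 9 & patients$iss < 16] <-
    clinical$rr_death30_local_iss9to15
  rr[local & patients$iss < 9] <- clinical$rr_death30_local_issLT16
  pmin(1, d * rr)
}

#' Probability of death between 30 days and 1 year post-injury
#'
#' ISS >= 16 with MTC care: 3.6%; ISS >= 16 never at an MTC: 3.6% x 1.64;
#' ISS < 16: 1.7% (with the ISS 9--15 scenario relative risk applied to
#' local-only patients when active). Capped at 1.
#'
#' @param iss Integer ISS vector.
#' @param ever_mtc Logical vector.
#' @param clinical `clinical` section of a `trauma_params`.
#' @return Vector of probabilities.
#' @export
p_death_30d_to_1yr <- function(iss, ever_mtc, clinical) {
  p <- ifelse(iss >= 16, clinical$p_death_30d_1yr_iss16,
              clinical$p_death_30d_1yr_issLT16)
  rr <- rep(1, length(p))
  rr[!ever_mtc & iss >= 16] <- clinical$rr_1yr_local_iss16
  rr[!ever_mtc & iss >= 9 & iss < 16] <- clinical$rr_1yr_local_iss9to15
  pmin(1, p * rr)
}

#' Generate a synthetic national life table
#'
#' Gompertz--Makeham annual death probabilities
#' `q(age) = 1 - exp(-(A + B * exp(theta * age)))` with sex-specific `B`.
#' The defaults approximate UK national life tables (period life expectancy
#' at birth ~79.3 male / ~82.5 female, at 65 ~18.0 / ~20.6). `q` is forced
#' to 1 at the cap so the lifetime simulation terminates. This is a
#' synthetic stand-in for the national tables, not a copy of them.
#'
#' @param cap Maximum age (default 100).
#' @param makeham Age-independent hazard component.
#' @param b_male,b_female Gompertz level parameters by sex.
#' @param theta Gompertz slope.
#' @return Data frame `age`, `sex` ("male"/"female"), `qx`.
#' @export
make_life_table <- function(cap = 100, makeham = 2e-4,
                            b_male = 1.4e-5, b_female = 1.0e-5,
                            theta = 0.105) {
  ages <- 0:cap
  q_of <- function(B) {
    q <- 1 - exp(-(makeham + B * exp(theta * ages)))
    q[length(q)] <- 1
    pmin(1, q)
  }
  rbind(
    data.frame(age = ages, sex = "male", qx = q_of(b_male)),
    data.frame(age = ages, sex = "female", qx = q_of(b_female))
  )
}

#' @rdname make_life_table
#' @param path CSV path (`age,sex,qx`).
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname make_life_table
#' @param life_table Life table data frame.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    stop("life table must have columns age,sex,qx", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) stop("qx outside [0, 1]", call. = FALSE)
  lt
}

# age x sex matrix lookup for fast vectorised access
life_table_matrix <- function(life_table) {
  cap <- max(life_table$age)
  m <- matrix(NA_real_, nrow = cap + 1L, ncol = 2L,
              dimnames = list(NULL, c("male", "female")))
  for (s in c("male", "female")) {
    sub <- life_table[life_table$sex == s, ]
    m[sub$age + 1L, s] <- sub$qx
  }
  if (anyNA(m)) stop("life table must cover all integer ages 0..cap for both sexes",
                     call. = FALSE)
  if (any(m[nrow(m), ] < 1)) stop("life table must have q = 1 at the age cap",
                                  call. = FALSE)
  m
}

#' Annual death probability under a trauma hazard ratio
#'
#' Applies a hazard ratio to a life-table annual death probability on the
#' survival scale: `q' = 1 - (1 - q)^hr`, clipped to \[0, 1\].
#'
#' @param age Integer age(s); must be within the table.
#' @param male 0/1 or logical vector.
#' @param hr Hazard ratio (>= 0).
#' @param life_table Data frame from [make_life_table()] / [read_life_table()].
#' @return Vector of adjusted probabilities.
#' @export
#' @examples
#' lt <- make_life_table()
#' annual_death_prob(70, 1, 5.19, lt)
annual_death_prob <- function(age, male, hr, life_table) {
  m <- life_table_matrix(life_table)
  if (any(age < 0 | age > nrow(m) - 1L)) {
    stop("age beyond life table cap", call. = FALSE)
  }
  q <- ifelse(male > 0, m[age + 1L, "male"], m[age + 1L, "female"])
  pmin(1, pmax(0, 1 - (1 - q)^hr))
}

#' Simulate age at death for 1-year survivors
#'
#' Annual Bernoulli walk from one year post-injury. Each year the patient
#' faces the hazard-ratio-adjusted life-table probability; death is placed
#' mid-cycle, so a patient dying in cycle `t` has death age
#' `age + t + 0.5`. Implemented by inverting each patient's cumulative
#' survival curve with a single uniform draw, which gives the same marginal
#' law as year-by-year Bernoulli draws and couples the walk monotonically
#' in the hazard ratio (larger `hr` can only bring death forward for the
#' same draw).
#'
#' @param age Age at injury (vector).
#' @param male 0/1 vector.
#' @param hr Hazard ratio vector (e.g. 5.19 for ISS >= 16, 1.38 otherwise).
#' @param life_table Life table data frame.
#' @param u One uniform draw per patient.
#' @return Vector of death ages (years); at most `cap + 0.5`.
#' @export
simulate_death_age <- function(age, male, hr, life_table, u) {
  stopifnot(length(u) == length(age), all(u >= 0 & u <= 1))
  u <- pmax(u, .Machine$double.eps)  # u = 0 would never cross the survival curve
  m <- life_table_matrix(life_table)
  cap <- nrow(m) - 1L
  n <- length(age)
  male_col <- ifelse(male > 0, 1L, 2L)
  base_age <- pmin(floor(age), cap)
  surv <- rep(1, n)
  death_cycle <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  t <- 1L
  while (any(alive)) {
    a <- pmin(base_age[alive] + t, cap)
    q <- m[cbind(a + 1L, male_col[alive])]
    q <- 1 - (1 - q)^hr[alive]
    surv[alive] <- surv[alive] * (1 - q)
    died <- alive
    died[alive] <- surv[alive] < u[alive]
    death_cycle[died] <- t
    alive[died] <- FALSE
    t <- t + 1L
    if (t > cap + 2L) { # safety: q(cap)=1 guarantees termination before this
      death_cycle[alive] <- t
      break
    }
  }
  age + death_cycle + 0.5
}
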