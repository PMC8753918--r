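# Shared fixtures: built in code, small, deterministic.

default_p <- default_parameters()

# flat life table: constant annual death probability q, q = 1 at the cap
flat_life_table <- function(q, cap = 100) {
  lt <- make_life_table(cap)
  lt$qx <- q
  lt$qx[lt$age == cap] <- 1
  lt
}

# flat NHS cost schedule: one annual cost at every age/sex
flat_cost_schedule <- function(annual_cost, cap = 100) {
  rbind(
    data.frame(age_lo = 0, age_hi = cap, sex = "male", annual_cost = annual_cost),
    data.frame(age_lo = 0, age_hi = cap, sex = "female", annual_cost = annual_cost)
  )
}

# utility parameters giving constant utility 1 at all ages (for closed forms)
unit_utility <- within(default_p$utility, {
  ara_constant <- 1; ara_age <- 0; ara_age2 <- 0; ara_male <- 0
  u_iss9plus <- 1
})

# PSA spec list with every parameter degenerate at its point estimate
fixed_dists <- function(params) {
  lapply(psa_distributions(params), function(d) dist_fixed(dist_mean(d)))
}

# parameter set with no MTC survival benefit and destination-independent costs
null_effect_params <- function(params = default_p) {
  params$clinical$rr_death30_local_iss16 <- 1
  params$clinical$rr_1yr_local_iss16 <- 1
  params$clinical$hr_longterm_iss16 <- 1
  params$clinical$hr_longterm_issLT16 <- 1
  params$cost$mtc_admit_iss16 <- 0
  params$cost$mtc_admit_iss9to15 <- 0
  params$cost$transfer_cost <- 0
  params
}
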