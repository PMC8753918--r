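model <- default_p$survival_model
clin <- default_p$clinical

test_that("30-day survival equals the closed-form inverse logit", {
  pts <- data.frame(age = c(30, 70, 46.8), iss = c(4, 50, 9),
                    gcs = c(15, 3, 14), male = c(1, 0, 1))
  b <- model$coefficients
  lp <- b[["intercept"]] + b[["age"]] * pts$age + b[["iss"]] * pts$iss +
    b[["gcs"]] * pts$gcs + b[["male"]] * pts$male
  expect_equal(p_survival_30d(pts, model), 1 / (1 + exp(-lp)), tolerance = 1e-12)
  expect_true(all(p_survival_30d(pts, model) > 0 &
                    p_survival_30d(pts, model) < 1))
  # monotone: minor injury survives more than severe at equal age/sex
  minor <- data.frame(age = 30, iss = 4, gcs = 15, male = 1)
  severe <- data.frame(age = 30, iss = 50, gcs = 3, male = 1)
  expect_gt(p_survival_30d(minor, model), p_survival_30d(severe, model))
  # zero linear predictor is the logistic fixed point
  m0 <- list(form = "logit_linear",
             coefficients = c(intercept = 0, age = 0, iss = 0, gcs = 0, male = 0))
  expect_equal(p_survival_30d(minor, m0), 0.5)
  expect_error(p_survival_30d(minor, list(form = "logit_linear",
                                          coefficients = c(intercept = 1))),
               "missing coefficient")
})

test_that("the local-hospital relative risk applies only to severe local patients", {
  ps <- 0.9
  pt16 <- data.frame(age = 40, iss = 20, gcs = 12, male = 1)
  ptlt <- data.frame(age = 40, iss = 5, gcs = 15, male = 1)
  expect_equal(p_death_30d(pt16, FALSE, clin, model, ps = ps), 0.125)
  expect_equal(p_death_30d(pt16, TRUE, clin, model, ps = ps), 0.1)
  expect_equal(p_death_30d(ptlt, FALSE, clin, model, ps = ps), 0.1)
  # capped at 1
  expect_equal(p_death_30d(pt16, FALSE, clin, model, ps = 0.1), 1)
})

test_that("30-day-to-1-year probabilities match the published table", {
  expect_equal(p_death_30d_to_1yr(20, TRUE, clin), 0.036)
  expect_equal(p_death_30d_to_1yr(20, FALSE, clin), 0.036 * 1.64)
  expect_equal(p_death_30d_to_1yr(5, TRUE, clin), 0.017)
  expect_equal(p_death_30d_to_1yr(5, FALSE, clin), 0.017)
})

test_that("hazard ratios transform annual death probabilities on the survival scale", {
  lt <- flat_life_table(0.01)
  expect_equal(annual_death_prob(50, 1, 1, lt), 0.01)
  expect_equal(annual_death_prob(50, 1, 5.19, lt), 1 - 0.99^5.19,
               tolerance = 1e-12)
  expect_equal(annual_death_prob(50, 0, 1.38, lt), 1 - 0.99^1.38,
               tolerance = 1e-12)
  expect_equal(round(annual_death_prob(50, 1, 5.19, lt), 4), 0.0508)
  expect_equal(round(annual_death_prob(50, 1, 1.38, lt), 4), 0.0138)
  expect_error(annual_death_prob(150, 1, 1, lt), "cap")
})

test_that("certain death tables kill in the first cycle", {
  lt <- flat_life_table(1)
  da <- simulate_death_age(c(40, 60), c(1, 0), c(1, 1), lt, c(0.5, 0.9))
  expect_equal(da, c(41.5, 61.5))
})

test_that("simulated death ages reproduce life-table expectancy at hr = 1", {
  lt <- make_life_table()
  start <- 47
  # independent standard life-table expectancy from the same table
  q <- lt$qx[lt$sex == "male" & lt$age > start]
  e_lt <- sum(cumprod(1 - q)) + 0.5
  set.seed(61)
  n <- 20000
  da <- simulate_death_age(rep(start, n), rep(1, n), rep(1, n), lt, runif(n))
  years <- da - start - 1  # walk starts one year post-injury
  expect_lt(abs(mean(years) - e_lt), 3 * sd(years) / sqrt(n))
})

test_that("survival is stochastically ordered by the hazard ratio", {
  lt <- make_life_table()
  set.seed(62)
  n <- 5000
  u <- runif(n)
  d_low <- simulate_death_age(rep(47, n), rep(1, n), rep(1.38, n), lt, u)
  d_high <- simulate_death_age(rep(47, n), rep(1, n), rep(5.19, n), lt, u)
  expect_true(all(d_high <= d_low))  # coupled draws: monotone in hr
  expect_lt(mean(d_high), mean(d_low))
  expect_true(all(d_low <= 101))
})

test_that("30-day mortality from simulation matches the analytic probability", {
  set.seed(63)
  n <- 5e4
  co <- sample_cohort(n, cohort_spec(), seed = 63)
  d <- p_death_30d(co, rep(TRUE, n), clin, model)
  died <- runif(n) < d
  se <- sqrt(sum(d * (1 - d))) / n
  expect_lt(abs(mean(died) - mean(d)), 3 * se)
  # calibrated near the reported cohort mortality range
  expect_gt(mean(d), 0.03)
  expect_lt(mean(d), 0.06)
})

test_that("life table fixtures are well-formed", {
  lt <- make_life_table()
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$qx[lt$age == 100], c(1, 1))
  for (s in c("male", "female")) {
    q <- lt$qx[lt$sex == s & lt$age >= 30]
    expect_true(all(diff(q) > 0))  # mortality increases beyond age 30
  }
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_equal(read_life_table(path), lt, tolerance = 1e-12)
})
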