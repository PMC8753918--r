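test_that("extended dominance is detected in the worked three-strategy example", {
  x <- data.frame(tool = c("A", "C", "B"),
                  qalys = c(10, 10.5, 11), costs = c(100, 190, 200))
  fr <- incremental_analysis(x)
  expect_equal(fr$status[fr$tool == "C"], "extendedly dominated")
  expect_equal(fr$status[fr$tool == "A"], "comparator")
  expect_equal(fr$status[fr$tool == "B"], "frontier")
  expect_equal(fr$icer[fr$tool == "B"], 100)
})

test_that("simple dominance and ties resolve as documented", {
  x <- data.frame(tool = c("A", "B"), qalys = c(10, 10), costs = c(100, 150))
  fr <- incremental_analysis(x)
  expect_equal(fr$status[fr$tool == "B"], "dominated")
  expect_equal(fr$status[fr$tool == "A"], "comparator")
  # exact tie: the first-listed strategy is kept
  x <- data.frame(tool = c("B", "A"), qalys = c(10, 10), costs = c(100, 100))
  fr <- incremental_analysis(x)
  expect_equal(fr$status[fr$tool == "B"], "comparator")
  expect_equal(fr$status[fr$tool == "A"], "dominated")
  # single strategy: comparator, no ICER
  fr <- incremental_analysis(data.frame(tool = "A", qalys = 1, costs = 1))
  expect_equal(fr$status, "comparator")
  expect_true(is.na(fr$icer))
  expect_error(incremental_analysis(data.frame(tool = "A", qalys = NaN,
                                               costs = 1)), "finite")
})

test_that("frontier agrees with brute-force NMB search on random strategy sets", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    df <- data.frame(tool = paste0("S", 1:n),
                     qalys = runif(n, 5, 15), costs = runif(n, 1e3, 5e4))
    fr <- incremental_analysis(df)
    members <- fr$tool[fr$status %in% c("comparator", "frontier")]
    expect_setequal(members, frontier_oracle(df))
    expect_setequal(fr$tool[fr$status == "dominated"], dominated_oracle(df))
    icers <- fr$icer[fr$status == "frontier"]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
    # frontier invariant under input order
    perm <- sample(n)
    fr2 <- incremental_analysis(df[perm, ])
    rownames(fr) <- rownames(fr2) <- NULL
    expect_equal(as.data.frame(fr2), as.data.frame(fr), tolerance = 1e-12)
  }
})

test_that("the MAICER decision equals the net-monetary-benefit argmax", {
  set.seed(111)
  for (rep in 1:300) {
    n <- sample(2:6, 1)
    df <- data.frame(tool = paste0("S", 1:n),
                     qalys = runif(n, 5, 15), costs = runif(n, 1e3, 5e4))
    fr <- incremental_analysis(df)
    lambda <- runif(1, 100, 6e4)
    expect_equal(cost_effective_at(fr, lambda), nmb_argmax(df, lambda))
  }
  # boundary inclusive: an ICER exactly at the MAICER is accepted
  x <- data.frame(tool = c("A", "B"), qalys = c(10, 11), costs = c(0, 100))
  fr <- incremental_analysis(x)
  expect_equal(cost_effective_at(fr, 100), "B")
  expect_equal(cost_effective_at(fr, 99), "A")
})

test_that("the ISS 9-15 benefit scenario interpolates both relative risks", {
  p50 <- scenario_iss9to15_benefit(default_p, 0.5)
  expect_equal(p50$clinical$rr_1yr_local_iss9to15, 1.32)
  expect_equal(p50$clinical$rr_death30_local_iss9to15, 1.125)
  p75 <- scenario_iss9to15_benefit(default_p, 0.75)
  expect_equal(p75$clinical$rr_1yr_local_iss9to15, 1.48)
  p0 <- scenario_iss9to15_benefit(default_p, 0)
  expect_equal(p0, default_p)
  expect_error(scenario_iss9to15_benefit(default_p, 1.5), "fraction")
  # the scenario worsens outcomes for local-only moderate injuries only
  expect_gt(p_death_30d_to_1yr(12, FALSE, p50$clinical),
            p_death_30d_to_1yr(12, FALSE, default_p$clinical))
  expect_equal(p_death_30d_to_1yr(12, TRUE, p50$clinical),
               p_death_30d_to_1yr(12, TRUE, default_p$clinical))
  expect_equal(p_death_30d_to_1yr(5, FALSE, p50$clinical),
               p_death_30d_to_1yr(5, FALSE, default_p$clinical))
})

test_that("tariff re-pricing is exact and the identity grid reproduces the base case", {
  co <- sample_cohort(3000, cohort_spec(), seed = 84)
  out <- run_deterministic(co, default_p, seed = 84)
  base_fr <- incremental_analysis(out)
  grid <- tariff_threshold_grid(out, default_p,
                                iss16_tariffs = 2819, iss9to15_tariffs = 1466,
                                maicers = c(20000, 30000))
  for (i in seq_len(nrow(grid))) {
    expect_equal(grid$tool[i], cost_effective_at(base_fr, grid$maicer[i]))
  }
  # re-priced costs equal a fresh simulation with the altered tariffs
  p0 <- default_p
  p0$cost$mtc_admit_iss16 <- 0
  p0$cost$mtc_admit_iss9to15 <- 0
  out0 <- run_deterministic(co, p0, seed = 84)
  repriced <- out$mean_costs_disc - 2819 * out$p_mtc_iss16 -
    1466 * out$p_mtc_iss9to15
  expect_equal(repriced, out0$mean_costs_disc, tolerance = 1e-9)
  expect_error(tariff_threshold_grid(out, default_p, -5, 0), "non-negative")
})

test_that("lower MTC tariffs never select a less sensitive tool", {
  co <- sample_cohort(5000, cohort_spec(), seed = 94)
  out <- run_deterministic(co, default_p, seed = 94)
  fr16 <- c(1, 0.75, 0.5, 0.25, 0)
  grid <- tariff_threshold_grid(out, default_p,
                                iss16_tariffs = fr16 * 2819,
                                iss9to15_tariffs = 1466, maicers = 20000)
  sens <- out$sensitivity[match(grid$tool, out$tool)]
  # rows are ordered by decreasing tariff within the call above
  expect_true(all(diff(sens[order(-grid$iss16_tariff)]) >= 0))
})
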