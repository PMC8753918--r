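test_that("default parameters reproduce the published point estimates", {
  p <- default_p
  expect_equal(unlist(p$clinical$transfer),
               c(tp = 0.266, fn = 0.325, tn = 0.043, fp = 0.074))
  expect_equal(p$economics$discount_rate, 0.035)
  expect_equal(p$clinical$rr_death30_local_iss16, 1.25)
  expect_equal(p$clinical$hr_longterm_iss16, 5.19)
  expect_equal(p$cost$mtc_admit_iss16, 2819)
  expect_equal(p$cost$blunt_treatment_bands$cost, c(6198, 8989, 14205, 21173))
  expect_equal(p$cost$penetrating_treatment_bands$cost,
               c(6501, 6035, 9453, 12347, 16438))
  expect_equal(nrow(p$tools), 9)
  # ninth tool: low sensitivity / high specificity pair
  expect_equal(min(p$tools$sensitivity), 0.284)
  expect_equal(p$tools$specificity[p$tools$sensitivity == 0.284], 0.886)
})

test_that("validation rejects malformed configurations", {
  bad <- default_p
  bad$tools$sensitivity[1] <- 1.2
  expect_error(validate_parameters(bad), "probability")
  bad <- default_p
  bad$clinical$transfer$fn <- -0.1
  expect_error(validate_parameters(bad), "probability")
  bad <- default_p
  bad$cost$blunt_treatment_bands$lo[2] <- 10  # gap between bands
  expect_error(validate_parameters(bad), "gap")
  raw <- yaml::yaml.load_file(system.file("extdata", "default_params.yaml",
                                          package = "traumatriage"))
  raw$clinical$not_a_key <- 1
  expect_error(params_from_list(raw), "unknown key")
  raw$clinical$not_a_key <- NULL
  raw$utility$u_iss9plus <- NULL
  expect_error(params_from_list(raw), "missing required")
})

test_that("parameters round-trip losslessly through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(default_p, path)
  reloaded <- load_parameters(path)
  expect_equal(reloaded, default_p, tolerance = 1e-12)
})

test_that("relative-risk interpolation is linear, bounded and monotone", {
  expect_equal(interpolated_rr(1.64, 0.5), 1.32)
  expect_equal(interpolated_rr(1.64, 0.75), 1.48)
  expect_equal(interpolated_rr(1.64, 0), 1)
  expect_equal(interpolated_rr(1.64, 1), 1.64)
  expect_equal(interpolated_rr(1.25, 0.25), 1.0625)
  expect_error(interpolated_rr(1.64, 1.2), "fraction")
  expect_error(interpolated_rr(0.8, 0.5), "rr_full")
  f <- seq(0, 1, 0.1)
  expect_true(all(diff(interpolated_rr(1.64, f)) > 0))
  rr <- seq(1, 3, 0.25)
  expect_true(all(diff(interpolated_rr(rr, 0.4)) > 0))
})

test_that("PSA distributions are moment-matched to the point estimates", {
  dists <- psa_distributions(default_p)
  expect_equal(dist_mean(dists[["clinical.transfer.fn"]]), 0.325, tolerance = 1e-9)
  expect_equal(dist_mean(dists[["clinical.rr_death30_local_iss16"]]), 1.25,
               tolerance = 1e-9)
  expect_equal(dist_mean(dists[["cost.mtc_admit_iss16"]]), 2819, tolerance = 1e-9)
  expect_equal(dist_mean(dists[["utility.u_iss9plus"]]), 0.65, tolerance = 1e-9)
  # every spec, including tool sens/spec betas, matches its point value
  pt <- c(
    unlist(default_p$clinical$transfer),
    sapply(c("rr_death30_local_iss16", "rr_1yr_local_iss16",
             "hr_longterm_iss16", "hr_longterm_issLT16",
             "p_death_30d_1yr_iss16", "p_death_30d_1yr_issLT16"),
           function(k) default_p$clinical[[k]])
  )
  nm <- c(paste0("clinical.transfer.", c("tp", "fn", "tn", "fp")),
          paste0("clinical.", c("rr_death30_local_iss16", "rr_1yr_local_iss16",
                                "hr_longterm_iss16", "hr_longterm_issLT16",
                                "p_death_30d_1yr_iss16", "p_death_30d_1yr_issLT16")))
  for (i in seq_along(nm)) {
    expect_equal(dist_mean(dists[[nm[i]]]), unname(pt[i]), tolerance = 1e-9)
  }
  for (i in seq_len(nrow(default_p$tools))) {
    expect_equal(dist_mean(dists[[paste0("tools.sens.", i)]]),
                 default_p$tools$sensitivity[i], tolerance = 1e-9)
  }
})

test_that("drawn parameter sets are valid and vary", {
  set.seed(42)
  d1 <- draw_parameters(default_p)
  d2 <- draw_parameters(default_p)
  expect_s3_class(d1, "trauma_params")
  expect_silent(validate_parameters(d1))
  expect_false(identical(d1$clinical$transfer$fn, d2$clinical$transfer$fn))
  expect_false(identical(d1$tools$sensitivity, d2$tools$sensitivity))
  # point-estimate structure untouched
  expect_identical(d1$tools$label, default_p$tools$label)
  expect_identical(d1$economics, default_p$economics)
})

test_that("degenerate distribution specs reproduce the deterministic values", {
  dists <- fixed_dists(default_p)
  set.seed(1)
  drawn <- draw_parameters(default_p, dists)
  expect_equal(drawn, default_p, tolerance = 1e-12)
})
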