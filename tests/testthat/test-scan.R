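test_that("the AIC scan recovers the generating Vdose threshold", {
  # single n=400 draws scatter a few Gy around the truth; the median of a
  # handful of seeded replicates pins it down
  sel <- vapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(n = 400, seed = 50 + s))
    sc <- scan_vdose(co, rule = outcome_rule(2, 0), quiet = TRUE)
    expect_false(is.na(sc$selected_dose_gy))
    # selection invariant: minimal AIC among significant fits
    ok <- sc$results$converged & sc$results$p_slope < 0.05
    expect_equal(sc$selected_dose_gy,
                 sc$results$dose_gy[ok][which.min(sc$results$aic[ok])])
    sc$selected_dose_gy
  }, numeric(1))
  expect_lt(abs(median(sel) - 51.43), 2.5)
})

test_that("the scan is deterministic and refinement only improves the optimum", {
  co <- generate_cohort(cohort_spec(n = 300, seed = 52))
  a <- scan_vdose(co, rule = outcome_rule(2, 0), quiet = TRUE)
  b <- scan_vdose(co, rule = outcome_rule(2, 0), quiet = TRUE)
  expect_identical(a$results, b$results)
  expect_identical(a$selected_dose_gy, b$selected_dose_gy)

  coarse <- scan_vdose(co, rule = outcome_rule(2, 0), refine = FALSE,
                       quiet = TRUE)
  expect_lte(min(a$results$aic), min(coarse$results$aic) + 1e-9)
  expect_lt(abs(a$selected_dose_gy - coarse$selected_dose_gy), 1 + 1e-9)
})

test_that("scan handles degenerate and single-dose inputs", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 53))
  # single strongly predictive dose: that dose is selected
  one <- scan_vdose(co, rule = outcome_rule(2, 0), grid = 51.43,
                    refine = FALSE, quiet = TRUE)
  expect_equal(one$selected_dose_gy, 51.43)
  # all grades forced to one class
  flat <- as_cohort(lapply(co, function(r) {
    patient_record(r$patient_id, r$dvh, 0)
  }))
  expect_error(scan_vdose(flat, rule = outcome_rule(2, 0), quiet = TRUE),
               "degenerate")
})

test_that("the selected dose tracks the generating threshold across locations", {
  for (dstar in c(40, 51.43, 65)) {
    sel <- vapply(1:4, function(s) {
      spec <- cohort_spec(n = 500, seed = 600 + s,
                          truth = logistic_risk_model(-2.5, 4.3, dstar))
      sc <- scan_vdose(generate_cohort(spec), rule = outcome_rule(2, 0),
                       quiet = TRUE)
      sc$selected_dose_gy
    }, numeric(1))
    expect_lt(abs(mean(sel, na.rm = TRUE) - dstar), 3)
  }
})

test_that("labels independent of dose usually select nothing", {
  # family-wise false selection across a multi-dose grid runs near 17%,
  # so "usually absent" is asserted at 70%
  absent <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec(n = 120, seed = 5000 + s))
    g <- grades(co)
    gp <- with_seed(9000 + s, sample(g))
    co2 <- as_cohort(lapply(seq_along(co), function(i) {
      patient_record(co[[i]]$patient_id, co[[i]]$dvh, gp[i])
    }))
    sc <- scan_vdose(co2, rule = outcome_rule(2, 0),
                     grid = seq(5, 80, by = 5), refine = FALSE, quiet = TRUE)
    is.na(sc$selected_dose_gy)
  }, logical(1))
  expect_gte(mean(absent), 0.7)
})

test_that("Mann-Whitney comparison matches the brute-force U count", {
  # identical groups: no evidence of a difference
  co <- toy_cohort(rep(c(4, 7, 9), 2), c(0, 0, 0, 2, 2, 2))
  same <- compare_groups(co, function(r) r$covariates$val, outcome_rule(2, 0))
  expect_gt(same$p_value, 0.9)

  # fully separated groups: U = 0 for the lower group
  co2 <- toy_cohort(c(1, 2, 3, 10, 11, 12), c(2, 2, 2, 0, 0, 0))
  sep <- compare_groups(co2, function(r) r$covariates$val, outcome_rule(2, 0))
  expect_equal(sep$u, brute_force_u(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(sep$u, 0)

  # random small samples (with ties): exact agreement with all-pairs count
  set.seed(61)
  for (i in 1:20) {
    n1 <- sample(3:6, 1)
    n0 <- sample(3:6, 1)
    vals <- c(sample(1:8, n1, replace = TRUE), sample(1:8, n0, replace = TRUE))
    gr <- c(rep(2, n1), rep(0, n0))
    got <- compare_groups(toy_cohort(vals, gr),
                          function(r) r$covariates$val, outcome_rule(2, 0))
    expect_equal(got$u, brute_force_u(vals[1:n1], vals[(n1 + 1):(n1 + n0)]))
  }

  expect_error(
    compare_groups(toy_cohort(1:4, rep(0, 4)),
                   function(r) r$covariates$val, outcome_rule(2, 0)),
    "empty")
})

test_that("covariate screen fits each covariate and flags bad ones", {
  co <- generate_cohort(cohort_spec(n = 400, seed = 71))
  tab <- covariate_screen(co, rule = outcome_rule(2, 0))
  expect_equal(tab$covariate,
               c("age", "psa", "gleason_group", "prescribed_dose_gy"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$n == 400))

  # a covariate equal to the true linear predictor is detected
  tr <- attr(co, "truth")
  co2 <- as_cohort(lapply(seq_along(co), function(i) {
    r <- co[[i]]
    r$covariates$signal <- tr$true_v_predictor[i]
    r
  }))
  sig <- covariate_screen(co2, covariates = "signal", rule = outcome_rule(2, 0))
  expect_lt(sig$p, 0.001)

  # constant covariate errors as collinear
  co3 <- as_cohort(lapply(co, function(r) {
    r$covariates$flatc <- 1
    r
  }))
  expect_error(covariate_screen(co3, covariates = "flatc",
                                rule = outcome_rule(2, 0)), "collinear")
})
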