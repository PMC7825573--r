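test_that("cumulative curves enforce their invariants", {
  c1 <- dvh_curve("p1", c(0, 40, 80), c(1, 0.4, 0))
  expect_s3_class(c1, "dvh_curve")
  expect_identical(c1$cum_volume[1], 1)

  # non-monotone dose grid is a malformed DVH naming the patient
  expect_error(dvh_curve("bad1", c(0, 50, 30, 60), c(1, .6, .4, .2)), "bad1")
  # increasing cumulative volume is malformed
  expect_error(dvh_curve("bad2", c(0, 30, 60), c(1, 0.4, 0.5)), "bad2")
  # curves not starting at 0 Gy are left-extended with volume 1
  c2 <- dvh_curve("p2", c(10, 50), c(1, 0.3))
  expect_identical(c2$dose_gy[1], 0)
  expect_identical(c2$cum_volume[1], 1)
  # normalization rescales the leading volume to exactly 1
  c3 <- dvh_curve("p3", c(0, 40), c(250, 100))
  expect_equal(c3$cum_volume, c(1, 0.4))
})

test_that("cumulative and differential forms are mutual inverses", {
  c1 <- dvh_curve("p1", c(0, 40, 80), c(1, 0.4, 0))
  d1 <- cumulative_to_differential(c1)
  expect_equal(d1$v, c(0.6, 0.4))
  expect_equal(d1$bin_center_gy, c(20, 60))

  # uniform-dose organ: all mass in one bin near the step dose
  cu <- dvh_curve("u", c(0, 60, 60.001), c(1, 1, 0))
  du <- cumulative_to_differential(cu)
  expect_equal(sum(du$v), 1)
  expect_equal(du$bin_center_gy[which.max(du$v)], 60.0005, tolerance = 1e-9)

  # residual volume at the grid maximum is absorbed into a final bin
  cr <- dvh_curve("r", c(0, 40, 70), c(1, 0.5, 0.2))
  dr <- cumulative_to_differential(cr)
  expect_equal(sum(dr$v), 1, tolerance = 1e-12)
  expect_equal(dr$v[length(dr$v)], 0.2)
  expect_equal(max(dr$bin_center_gy), 70)

  expect_error(cumulative_to_differential(dvh_curve("s", 0, 1)), "grid")

  # round-trip identity on random curves
  set.seed(11)
  for (i in 1:50) {
    cv <- random_curve(sprintf("r%d", i))
    back <- differential_to_cumulative(cumulative_to_differential(cv))
    expect_equal(back$dose_gy, cv$dose_gy, tolerance = 1e-12)
    expect_equal(back$cum_volume, cv$cum_volume, tolerance = 1e-9)
  }

  # single-bin differential without a recorded grid becomes a step curve
  step <- differential_to_cumulative(differential_dvh(55, 1))
  expect_equal(step$dose_gy, c(0, 55))
  expect_equal(step$cum_volume, c(1, 0))
  expect_error(differential_dvh(c(10, 20), c(0.9, -0.1)), "negative")
})

test_that("volume_at_dose interpolates linearly and clamps beyond the grid", {
  c1 <- dvh_curve("p1", c(0, 40, 80), c(1, 0.4, 0))
  expect_identical(volume_at_dose(c1, 0), 1)
  expect_identical(volume_at_dose(c1, 200), 0)
  expect_equal(volume_at_dose(c1, 51.43), 0.2857, tolerance = 1e-12)
  expect_error(volume_at_dose(c1, -1), "non-negative")

  # non-increasing in dose for random curves
  set.seed(7)
  for (i in 1:50) {
    cv <- random_curve()
    v <- volume_at_dose(cv, sort(runif(40, 0, 90)))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("read_cohort parses, normalizes and validates the shipped fixture", {
  co <- read_cohort(extdata("dvh_3pt_synthetic.csv"),
                    extdata("outcomes_3pt_synthetic.csv"))
  expect_length(co, 3)
  for (r in co) expect_identical(r$dvh$cum_volume[1], 1)
  # cc volumes normalized by the 250 cc total: 180/250 at 30 Gy
  p3 <- co[[3]]
  expect_equal(p3$dvh$total_volume_cc, 250)
  expect_equal(volume_at_dose(p3$dvh, 30), 0.72, tolerance = 1e-12)
  expect_equal(volume_at_dose(p3$dvh, 55), 90 / 250, tolerance = 1e-12)
  # percent volumes divided by 100
  expect_equal(volume_at_dose(co[[1]]$dvh, 40), 0.55, tolerance = 1e-12)
  # covariates carried through
  expect_equal(co[[2]]$covariates$psa, 11.5)
})

test_that("read_cohort rejects malformed inputs with informative errors", {
  dvh_f <- withr::local_tempfile(fileext = ".csv")
  out_f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,dose_gy,volume,volume_unit",
               "A,0,1,fraction", "A,50,0.6,fraction", "A,30,0.8,fraction",
               "A,60,0.2,fraction"), dvh_f)
  writeLines(c("patient_id,grade", "A,1"), out_f)
  expect_error(read_cohort(dvh_f, out_f), "A.*not strictly increasing")

  writeLines(c("patient_id,dose_gy,volume,volume_unit",
               "A,0,1,fraction", "A,50,0.5,fraction"), dvh_f)
  writeLines(c("patient_id,grade", "A,7"), out_f)
  expect_error(read_cohort(dvh_f, out_f), "0..4")

  writeLines(c("patient_id,grade", "B,1"), out_f)
  expect_error(read_cohort(dvh_f, out_f), "no outcome row: A")
})

test_that("write-then-read round-trips a cohort", {
  co <- generate_cohort(cohort_spec(n = 12, seed = 3))
  dvh_f <- withr::local_tempfile(fileext = ".csv")
  out_f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, dvh_f, out_f)
  back <- read_cohort(dvh_f, out_f)
  expect_length(back, length(co))
  ids <- vapply(co, function(r) r$patient_id, character(1))
  for (r in back) {
    orig <- co[[match(r$patient_id, ids)]]
    expect_equal(r$dvh$cum_volume, orig$dvh$cum_volume, tolerance = 1e-9)
    expect_identical(r$grade, orig$grade)
  }
  # writer output is bit-stable: a rewrite is byte-identical
  dvh_f2 <- withr::local_tempfile(fileext = ".csv")
  out_f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, dvh_f2, out_f2)
  write_cohort(read_cohort(dvh_f2, out_f2), dvh_f, out_f)
  expect_identical(readLines(dvh_f), readLines(dvh_f2))
  expect_identical(readLines(out_f), readLines(out_f2))
})
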