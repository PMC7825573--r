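test_that("AUC matches the all-pairs definition", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:5, rep(1, 5)), "degenerate")

  set.seed(81)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    s <- sample(1:6, n, replace = TRUE)   # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), brute_force_auc(s, y), tolerance = 1e-12)
  }
})

test_that("AUC respects its symmetry and rank-invariance properties", {
  set.seed(82)
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  expect_equal(auc(s, y) + auc(-s, y), 1, tolerance = 1e-12)
  expect_equal(auc(s, y), auc(exp(s), y), tolerance = 1e-12)
  expect_equal(auc(s, y), auc(qlogis(plogis(s)), y), tolerance = 1e-9)
})

test_that("Hosmer-Lemeshow reproduces a hand-computed example", {
  probs <- rep(c(0.1, 0.2, 0.3, 0.4), each = 5)
  labels <- c(c(1, 0, 0, 0, 0),          # O = 1, E = 0.5
              rep(0, 5),                 # O = 0, E = 1.0
              c(1, 1, 0, 0, 0),          # O = 2, E = 1.5
              c(1, 1, 1, 0, 0))          # O = 3, E = 2.0
  hl <- hosmer_lemeshow(probs, labels, bins = 4)
  hand <- 0.25 / (0.5 * (1 - 0.5 / 5)) + 1 / (1 * (1 - 1 / 5)) +
    0.25 / (1.5 * (1 - 1.5 / 5)) + 1 / (2 * (1 - 2 / 5))
  expect_equal(hl$chi2, hand, tolerance = 1e-9)
  expect_equal(hl$df, 2L)
  expect_equal(hl$p, pchisq(hand, 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow separates calibrated from miscalibrated models", {
  # well-calibrated: p rarely below 0.05
  set.seed(83)
  ps <- replicate(60, {
    x <- runif(1000)
    y <- rbinom(1000, 1, plogis(-2.5 + 4.3 * x))
    f <- fit_logistic_univariate(x, y)
    hosmer_lemeshow(plogis(f$intercept + f$slope * x), y, quiet = TRUE)$p
  })
  expect_gt(mean(ps > 0.05), 0.8)

  # systematically halved probabilities: decisive lack of fit
  set.seed(84)
  x <- runif(5000)
  p_true <- plogis(-1 + 2 * x)
  y <- rbinom(5000, 1, p_true)
  expect_lt(hosmer_lemeshow(p_true / 2, y, quiet = TRUE)$p, 0.001)
})

test_that("HL p-values are near-uniform under the true model", {
  set.seed(85)
  ps <- replicate(300, {
    x <- runif(2000)
    y <- rbinom(2000, 1, plogis(-2.5 + 4.3 * x))
    f <- fit_logistic_univariate(x, y)
    hosmer_lemeshow(plogis(f$intercept + f$slope * x), y, quiet = TRUE)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("calibration curve tracks the diagonal for calibrated predictions", {
  set.seed(86)
  x <- runif(5000)
  p <- plogis(-2.5 + 4.3 * x)
  y <- rbinom(5000, 1, p)
  cc <- calibration_curve(p, y, bins = 10)
  expect_equal(sum(cc$n), 5000)
  expect_lt(max(abs(cc$mean_pred - cc$obs_rate)), 0.1)

  # all-negative labels: observed rate 0 everywhere
  cc0 <- calibration_curve(runif(100, 0.1, 0.9), rep(0, 100), bins = 5)
  expect_true(all(cc0$obs_rate == 0))

  # two bins on four points, checked by hand
  cc2 <- calibration_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), bins = 2)
  expect_equal(cc2$mean_pred, c(0.15, 0.85))
  expect_equal(cc2$obs_rate, c(0, 1))
  expect_equal(cc2$n, c(2, 2))
})

test_that("bootstrap validation is seeded, stable and honest about the null", {
  co <- generate_cohort(cohort_spec(n = 175, seed = 91))

  one <- bootstrap_validate(co, 51.43, outcome_rule(2, 0), B = 1, seed = 5)
  two <- bootstrap_validate(co, 51.43, outcome_rule(2, 0), B = 1, seed = 5)
  expect_identical(one$auc_distribution, two$auc_distribution)

  va <- bootstrap_validate(co, 51.43, outcome_rule(2, 0), B = 1000, seed = 1)
  vb <- bootstrap_validate(co, 51.43, outcome_rule(2, 0), B = 1000, seed = 2)
  expect_length(va$auc_distribution, 1000)
  expect_equal(va$auc_median, median(va$auc_distribution))
  expect_lt(abs(va$auc_median - vb$auc_median), 0.02)
  expect_gt(va$auc_apparent, 0.6)   # real signal in this cohort

  # labels independent of the predictor: AUC near 1/2
  g <- grades(co)
  gp <- with_seed(99, sample(g))
  con <- as_cohort(lapply(seq_along(co), function(i) {
    patient_record(co[[i]]$patient_id, co[[i]]$dvh, gp[i])
  }))
  v0 <- bootstrap_validate(con, 51.43, outcome_rule(2, 0), B = 400, seed = 3)
  expect_lt(abs(v0$auc_median - 0.5), 0.07)
})

test_that("median-AUC spread across seeds shrinks as B grows", {
  co <- generate_cohort(cohort_spec(n = 150, seed = 92))
  med <- function(B, seed) {
    bootstrap_validate(co, 51.43, outcome_rule(2, 0), B = B,
                       seed = seed)$auc_median
  }
  m100 <- vapply(1:10, function(s) med(100, s), numeric(1))
  m1000 <- vapply(1:10, function(s) med(1000, 100 + s), numeric(1))
  expect_lt(sd(m1000), sd(m100) + 1e-9)
})

test_that("pROC agrees with the rank AUC on a realistic cohort", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_spec(n = 200, seed = 93))
  tr <- attr(co, "truth")
  ref <- as.numeric(pROC::auc(pROC::roc(tr$y, tr$true_v_predictor,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc(tr$true_v_predictor, tr$y), ref, tolerance = 1e-12)
})
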