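# Independent oracles and fixture builders shared across test files.

# All-pairs AUC: P(score_pos > score_neg) with ties counted 1/2.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# All-pairs Mann-Whitney U for the first sample.
brute_force_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) {
    u <- u + (a > b) + 0.5 * (a == b)
  }
  u
}

# Two-stage grid maximization of the Bernoulli log-likelihood of a
# univariate logistic model; independent of glm.
grid_logistic_mle <- function(x, y) {
  ll <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - log1p(exp(eta)))
  }
  best <- c(0, 0)
  best_ll <- -Inf
  for (b in seq(-10, 10, by = 0.05)) {
    for (a in seq(-8, 8, by = 0.05)) {
      v <- ll(a, b)
      if (v > best_ll) {
        best_ll <- v
        best <- c(a, b)
      }
    }
  }
  for (b in seq(best[2] - 0.06, best[2] + 0.06, by = 0.001)) {
    for (a in seq(best[1] - 0.06, best[1] + 0.06, by = 0.001)) {
      v <- ll(a, b)
      if (v > best_ll) {
        best_ll <- v
        best <- c(a, b)
      }
    }
  }
  list(intercept = best[1], slope = best[2], loglik = best_ll)
}

# Random valid cumulative DVH curve on a random grid.
random_curve <- function(id = "r", n_points = sample(5:30, 1)) {
  d <- c(0, sort(runif(n_points - 1, 0.5, 80)))
  cv <- c(1, sort(runif(n_points - 1), decreasing = TRUE) * runif(1, 0.3, 1))
  dvh_curve(id, d, cv, normalize = FALSE)
}

# Flat-DVH patient carrying a scalar covariate, for group-comparison toys.
toy_record <- function(id, value, grade) {
  patient_record(id, dvh_curve(id, c(0, 60), c(1, 0.5)), grade,
                 covariates = list(val = value))
}

toy_cohort <- function(values, grades_vec) {
  as_cohort(mapply(toy_record, sprintf("T%03d", seq_along(values)),
                   values, grades_vec, SIMPLIFY = FALSE))
}

extdata <- function(...) system.file("extdata", ..., package = "dvhtox")
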