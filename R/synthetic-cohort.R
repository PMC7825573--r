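#' Specification of a synthetic DVH cohort
#'
#' Defines the generating process for a synthetic bladder-DVH cohort with
#' the statistical structure the analysis assumes: per-patient sigmoid
#' cumulative DVHs (location `d50` normal across patients, steepness `w`
#' log-normal), a logistic dose-response truth model on the volume fraction
#' at the predictor dose, and a conditional grade mixture splitting
#' positives into grades 2-4 and negatives into grades 0-1.
#'
#' Defaults emulate a 175-patient cohort: `d50 ~ N(55, 8)` Gy and
#' `w ~ LogNormal(log 6, 0.25)` make V51.43 span roughly (0.05, 0.95)
#' across patients, giving the Vdose scan contrast; the truth model is the
#' published a = -2.5, b = 4.3 on V51.43; the grade mixture follows the
#' published grade distribution (negatives 118:43 into G0:G1, positives
#' 9:4:1 into G2:G3:G4).
#'
#' @param n cohort size (default 175).
#' @param mu_d50,sd_d50 mean and SD (Gy) of the DVH location parameter.
#' @param meanlog_w,sdlog_w log-scale parameters of the DVH steepness (Gy).
#' @param truth a [logistic_risk_model()] generating the outcomes.
#' @param grade_mixture list with `negative` (probabilities over grades 0-1)
#'   and `positive` (over grades 2-4), each summing to 1.
#' @param grid dose grid (Gy) the DVHs are evaluated on; must start at 0.
#' @param seed RNG seed; the cohort is fully determined by the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 175, mu_d50 = 55, sd_d50 = 8,
                        meanlog_w = log(6), sdlog_w = 0.25,
                        truth = logistic_risk_model(),
                        grade_mixture = list(
                          negative = c(`0` = 118 / 161, `1` = 43 / 161),
                          positive = c(`2` = 9 / 14, `3` = 4 / 14, `4` = 1 / 14)),
                        grid = seq(0, 85, by = 0.5),
                        seed = 1) {
  if (n < 1) stopf("cohort_spec: n must be at least 1")
  stopifnot(inherits(truth, "logistic_risk_model"))
  if (sd_d50 <= 0 || sdlog_w < 0) stopf("cohort_spec: dispersion parameters must be positive")
  if (grid[1] != 0 || any(diff(grid) <= 0)) {
    stopf("cohort_spec: dose grid must start at 0 and increase")
  }
  for (part in c("negative", "positive")) {
    p <- grade_mixture[[part]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stopf("cohort_spec: grade_mixture$%s must be probabilities summing to 1",
            part)
    }
  }
  structure(
    list(n = as.integer(n), mu_d50 = mu_d50, sd_d50 = sd_d50,
         meanlog_w = meanlog_w, sdlog_w = sdlog_w, truth = truth,
         grade_mixture = grade_mixture, grid = grid,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: n = %d, d50 ~ N(%.3g, %.3g) Gy, w ~ LN(%.3g, %.3g)\n",
    x$n, x$mu_d50, x$sd_d50, x$meanlog_w, x$sdlog_w))
  cat(sprintf("  truth: a = %.3g, b = %.3g on V%.4g; seed = %d\n",
              x$truth$intercept, x$truth$slope, x$truth$predictor_dose_gy,
              x$seed))
  invisible(x)
}

#' Generate one sigmoid cumulative DVH
#'
#' Cumulative volume \eqn{(1 + e^{(d - d_{50})/w})^{-1}}, rescaled so the
#' curve is exactly 1 at 0 Gy; monotone non-increasing by construction.
#' A two-parameter family: `d50` shifts the falloff, `w` controls its
#' steepness.
#'
#' @param patient_id identifier.
#' @param d50 dose (Gy) at which the raw sigmoid reaches half volume.
#' @param w steepness (Gy), positive.
#' @param grid dose grid starting at 0 (Gy).
#' @return A [dvh_curve()].
#' @export
generate_dvh <- function(patient_id, d50, w, grid = seq(0, 85, by = 0.5)) {
  if (!is.finite(w) || w <= 0) stopf("generate_dvh: steepness w must be positive")
  raw <- stats::plogis(-(grid - d50) / w)
  dvh_curve(patient_id, grid, raw / raw[1], normalize = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient DVH parameters, computes the true predictor
#' \eqn{V_i} = volume fraction at the truth model's predictor dose, draws
#' the toxicity indicator \eqn{y_i \sim Bernoulli(P(V_i))} under the truth
#' model, and assigns a grade from the conditional mixture. Independent
#' clinical covariates (age, PSA, Gleason group, prescribed dose) are
#' attached for covariate-screen testing. Fully determined by
#' `spec$seed`; the generating truth is attached as attribute `"truth"`
#' (data frame: `patient_id`, `true_v_predictor`, `p_true`, `y`) for
#' oracle tests.
#'
#' @param spec a [cohort_spec()].
#' @return A `dvh_cohort` with attributes `truth`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  with_seed(spec$seed, {
    d50 <- pmax(stats::rnorm(n, spec$mu_d50, spec$sd_d50), 5)
    w <- stats::rlnorm(n, spec$meanlog_w, spec$sdlog_w)
    ids <- sprintf("P%04d", seq_len(n))
    curves <- lapply(seq_len(n), function(i) {
      generate_dvh(ids[i], d50[i], w[i], spec$grid)
    })
    v <- vapply(curves, volume_at_dose, numeric(1),
                dose = spec$truth$predictor_dose_gy)
    p_true <- logistic_risk(v, spec$truth)
    y <- stats::rbinom(n, 1L, p_true)
    neg <- spec$grade_mixture$negative
    pos <- spec$grade_mixture$positive
    grade <- integer(n)
    for (i in seq_len(n)) {
      grade[i] <- if (y[i] == 1L) {
        as.integer(sample(names(pos), 1L, prob = pos))
      } else {
        as.integer(sample(names(neg), 1L, prob = neg))
      }
    }
    age <- round(pmin(pmax(stats::rnorm(n, 72, 6), 50), 90))
    psa <- round(stats::rlnorm(n, log(8), 0.6), 2)
    gleason <- sample(1:5, n, replace = TRUE,
                      prob = c(42.3, 29.7, 12.6, 11.4, 4) / 100)
    pdose <- sample(c(80, 67.5, 73.8), n, replace = TRUE,
                    prob = c(139, 21, 15) / 175)
    records <- lapply(seq_len(n), function(i) {
      patient_record(ids[i], curves[[i]], grade[i],
                     covariates = list(age = age[i], psa = psa[i],
                                       gleason_group = gleason[i],
                                       prescribed_dose_gy = pdose[i]))
    })
    cohort <- as_cohort(records)
    attr(cohort, "truth") <- data.frame(
      patient_id = ids, true_v_predictor = v, p_true = p_true, y = y,
      stringsAsFactors = FALSE)
    attr(cohort, "spec") <- spec
    cohort
  })
}

#' Summarize a cohort
#'
#' Grade counts with percentages (two decimals), quartiles of the Vdose
#' predictor, and mean bladder dose by grade.
#'
#' @param cohort a `dvh_cohort`.
#' @param v_dose dose level (Gy) for the Vdose summary (default 51.43).
#' @return An object of class `cohort_summary`: `n`, `grade_table`
#'   (grade, count, percent), `vdose_gy`, `v_quartiles`,
#'   `mean_dose_by_grade`.
#' @export
cohort_summary <- function(cohort, v_dose = 51.43) {
  cohort <- as_cohort(cohort)
  g <- grades(cohort)
  n <- length(g)
  counts <- tabulate(g + 1L, nbins = 5L)
  grade_table <- data.frame(
    grade = 0:4, count = counts,
    percent = round_half_up(100 * counts / n, 2))
  v <- cohort_vdose(cohort, v_dose)
  md <- vapply(cohort, mean_dose, numeric(1))
  structure(
    list(n = n, grade_table = grade_table, vdose_gy = v_dose,
         v_quartiles = stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1)),
         mean_dose_by_grade = tapply(md, factor(g, levels = 0:4), mean)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat("Late toxicity grades:\n")
  for (i in seq_len(nrow(x$grade_table))) {
    cat(sprintf("  G%d  %4d (%.2f%%)\n", x$grade_table$grade[i],
                x$grade_table$count[i], x$grade_table$percent[i]))
  }
  cat(sprintf("V%.4g quartiles: %s\n", x$vdose_gy,
              paste(sprintf("%.3f", x$v_quartiles), collapse = " ")))
  invisible(x)
}

#' Write a synthetic cohort with its generating truth
#'
#' Emits the standard DVH/outcome CSV dialects plus a truth CSV
#' (`patient_id`, `true_v_predictor`, `p_true`, `y`) and the spec as JSON,
#' for oracle tests against the generated data.
#'
#' @param cohort a generated `dvh_cohort` (from [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dvh_cohort"))
  truth <- attr(cohort, "truth")
  spec <- attr(cohort, "spec")
  if (is.null(truth) || is.null(spec)) {
    stopf("write_synthetic_cohort: cohort lacks generation attributes")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dvh = file.path(dir, "dvh.csv"),
    outcome = file.path(dir, "outcomes.csv"),
    truth = file.path(dir, "truth.csv"),
    spec = file.path(dir, "cohort_spec.json")
  )
  write_cohort(cohort, paths[["dvh"]], paths[["outcome"]])
  utils::write.csv(truth[order(truth$patient_id), ], paths[["truth"]],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = spec$n, mu_d50 = spec$mu_d50, sd_d50 = spec$sd_d50,
         meanlog_w = spec$meanlog_w, sdlog_w = spec$sdlog_w,
         truth = list(intercept_a = spec$truth$intercept,
                      slope_b = spec$truth$slope,
                      predictor_dose_gy = spec$truth$predictor_dose_gy),
         grade_mixture = spec$grade_mixture,
         grid = list(from = min(spec$grid), to = max(spec$grid),
                     by = spec$grid[2] - spec$grid[1]),
         seed = spec$seed),
    paths[["spec"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
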