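#' Outcome rule: endpoint and analysis subset by toxicity grade
#'
#' The published analysis dichotomizes grade >= 2 toxicity within the subset
#' of patients with any toxicity (grade >= 1); the full-cohort analysis uses
#' `subset_grade_ge = 0`.
#'
#' @param grade_ge grade threshold defining the positive outcome (default 2).
#' @param subset_grade_ge minimum grade for inclusion in the analysis subset
#'   (default 0, i.e. everyone).
#' @return An object of class `outcome_rule`.
#' @export
outcome_rule <- function(grade_ge = 2, subset_grade_ge = 0) {
  grade_ge <- as.integer(grade_ge)
  subset_grade_ge <- as.integer(subset_grade_ge)
  if (!grade_ge %in% 1:4 || !subset_grade_ge %in% 0:4 ||
      subset_grade_ge >= grade_ge) {
    stopf("outcome_rule: need 0 <= subset_grade_ge < grade_ge <= 4")
  }
  structure(list(grade_ge = grade_ge, subset_grade_ge = subset_grade_ge),
            class = "outcome_rule")
}

# subset indices and binary outcome under a rule
apply_outcome_rule <- function(cohort, rule) {
  stopifnot(inherits(rule, "outcome_rule"))
  g <- grades(cohort)
  keep <- which(g >= rule$subset_grade_ge)
  list(keep = keep, y = as.integer(g[keep] >= rule$grade_ge))
}

#' AIC-minimizing scan over candidate Vdose levels
#'
#' The central model-selection procedure: for every candidate dose d on a
#' grid, the per-patient predictor \eqn{x_i = V_d} (volume fraction at d) is
#' extracted and a univariate logistic model of the toxicity endpoint on
#' \eqn{x} is fitted; the dose whose model attains the lowest AIC among
#' those with a slope Wald p-value below `p_cutoff` is selected. Ties in
#' AIC go to the lowest dose. Doses at which the predictor is constant
#' across patients are skipped with a notice. An optional refinement pass
#' repeats the scan at `refine_step` resolution around the coarse optimum.
#' If no dose passes the significance cut the result carries no selected
#' dose (this is a reportable outcome, not an error).
#'
#' @param cohort a `dvh_cohort`.
#' @param rule an [outcome_rule()] (default grade >= 2 on the full cohort).
#' @param grid ascending candidate doses in Gy; default 1-Gy steps from
#'   5 Gy to the cohort's 99th-percentile maximum DVH dose.
#' @param refine run the refinement pass (default `TRUE`).
#' @param refine_step resolution of the refinement pass (Gy, default 0.1).
#' @param p_cutoff slope significance cut (default 0.05).
#' @param quiet suppress skip notices.
#' @return An object of class `vdose_scan`: `results` (data frame with one
#'   row per evaluated dose: `dose_gy`, `intercept`, `slope`, `se_slope`,
#'   `p_slope`, `aic`, `n_used`, `converged`), `selected_dose_gy` (`NA` if
#'   nothing passed), `selected_fit`, `selection_rule`, `skipped_gy`.
#' @export
scan_vdose <- function(cohort, rule = outcome_rule(2), grid = NULL,
                       refine = TRUE, refine_step = 0.1, p_cutoff = 0.05,
                       quiet = FALSE) {
  cohort <- as_cohort(cohort)
  sub <- apply_outcome_rule(cohort, rule)
  y <- sub$y
  if (length(unique(y)) < 2L) {
    stopf("scan_vdose: degenerate outcomes under this rule (single class)")
  }
  patients <- cohort[sub$keep]
  if (is.null(grid)) {
    dmax <- stats::quantile(
      vapply(patients, function(r) max(r$dvh$dose_gy), numeric(1)),
      0.99, names = FALSE)
    grid <- seq(5, floor(dmax), by = 1)
  }
  grid <- sort(unique(as.numeric(grid)))
  coarse_step <- if (length(grid) > 1L) min(diff(grid)) else 1

  scan_at <- function(doses) {
    v <- t(vapply(patients, function(r) volume_at_dose(r$dvh, doses),
                  numeric(length(doses))))
    if (length(doses) == 1L) v <- matrix(v, ncol = 1L)
    rows <- vector("list", length(doses))
    skipped <- numeric(0)
    for (j in seq_along(doses)) {
      x <- v[, j]
      if (diff(range(x)) < 1e-12) {
        skipped <- c(skipped, doses[j])
        next
      }
      f <- fit_logistic_univariate(x, y)
      rows[[j]] <- data.frame(
        dose_gy = doses[j], intercept = f$intercept, slope = f$slope,
        se_slope = f$se_slope, p_slope = f$wald_p_slope, aic = f$aic,
        n_used = f$n, converged = f$converged)
    }
    list(results = do.call(rbind, rows), skipped = skipped)
  }

  coarse <- scan_at(grid)
  res <- coarse$results
  skipped <- coarse$skipped
  if (is.null(res)) {
    stopf("scan_vdose: predictor constant at every grid dose")
  }

  select_from <- function(res) {
    ok <- res$converged & res$p_slope < p_cutoff
    if (!any(ok)) return(NA_real_)
    cand <- res[ok, , drop = FALSE]
    cand <- cand[order(cand$aic, cand$dose_gy), , drop = FALSE]
    cand$dose_gy[1]
  }

  sel <- select_from(res)
  if (refine && !is.na(sel) && refine_step < coarse_step) {
    fine <- seq(max(min(grid), sel - coarse_step),
                min(max(grid), sel + coarse_step), by = refine_step)
    fine <- setdiff(round(fine, 10), round(res$dose_gy, 10))
    if (length(fine) > 0L) {
      extra <- scan_at(fine)
      res <- rbind(res, extra$results)
      skipped <- c(skipped, extra$skipped)
      res <- res[order(res$dose_gy), , drop = FALSE]
      sel <- select_from(res)
    }
  }
  rownames(res) <- NULL
  sel_fit <- if (is.na(sel)) NULL else res[res$dose_gy == sel, , drop = FALSE]
  if (!quiet && length(skipped) > 0L) {
    message(sprintf("scan_vdose: skipped %d dose(s) with constant predictor",
                    length(skipped)))
  }
  structure(
    list(results = res, selected_dose_gy = sel, selected_fit = sel_fit,
         selection_rule = list(criterion = "minimum AIC", p_cutoff = p_cutoff,
                               tie_break = "lowest dose"),
         skipped_gy = sort(skipped), rule = rule, n_used = length(y)),
    class = "vdose_scan"
  )
}

#' @export
print.vdose_scan <- function(x, ...) {
  cat(sprintf("Vdose scan over %d dose levels (n = %d patients)\n",
              nrow(x$results), x$n_used))
  if (is.na(x$selected_dose_gy)) {
    cat(sprintf("No dose passed p < %.3g: no Vdose selected\n",
                x$selection_rule$p_cutoff))
  } else {
    f <- x$selected_fit
    cat(sprintf(
      "Selected Vdose = %.2f Gy (AIC %.3f, slope %.3f, p = %.4g)\n",
      x$selected_dose_gy, f$aic, f$slope, f$p_slope))
  }
  invisible(x)
}

#' Write a Vdose scan report to CSV
#'
#' @param scan a `vdose_scan`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_scan_report <- function(scan, file) {
  stopifnot(inherits(scan, "vdose_scan"))
  utils::write.csv(scan$results, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Mann-Whitney comparison of a dosimetric scalar between outcome groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test with normal
#' approximation, tie correction and continuity correction, comparing a
#' per-patient scalar (e.g. mean bladder dose, a Vdose value) between the
#' positive and negative outcome groups.
#'
#' @param cohort a `dvh_cohort`.
#' @param extractor function mapping a [patient_record()] to a scalar;
#'   default [mean_dose()].
#' @param rule an [outcome_rule()] defining the two groups.
#' @return List with `u` (U statistic for the positive group), `p_value`,
#'   group sizes `n_pos`, `n_neg`.
#' @export
compare_groups <- function(cohort, extractor = mean_dose,
                           rule = outcome_rule(2)) {
  cohort <- as_cohort(cohort)
  sub <- apply_outcome_rule(cohort, rule)
  vals <- vapply(cohort[sub$keep], extractor, numeric(1))
  pos <- vals[sub$y == 1]
  neg <- vals[sub$y == 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stopf("compare_groups: one of the outcome groups is empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(pos, neg, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_pos = length(pos), n_neg = length(neg))
}

#' Univariate logistic screen of clinical covariates
#'
#' One univariate logistic fit of the toxicity endpoint per covariate,
#' complete-case within covariate, with no multiplicity correction.
#'
#' @param cohort a `dvh_cohort` whose records carry covariates.
#' @param covariates covariate names to screen.
#' @param rule an [outcome_rule()].
#' @return Data frame with one row per covariate: estimate, SE, Wald p,
#'   AIC, number of complete cases.
#' @export
covariate_screen <- function(cohort,
                             covariates = c("age", "psa", "gleason_group",
                                            "prescribed_dose_gy"),
                             rule = outcome_rule(2)) {
  cohort <- as_cohort(cohort)
  sub <- apply_outcome_rule(cohort, rule)
  recs <- cohort[sub$keep]
  y <- sub$y
  rows <- lapply(covariates, function(nm) {
    x <- vapply(recs, function(r) {
      v <- r$covariates[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    if (all(is.na(x))) {
      stopf("covariate_screen: covariate '%s' is missing for every patient", nm)
    }
    cc <- !is.na(x)
    f <- fit_logistic_univariate(x[cc], y[cc])
    data.frame(covariate = nm, estimate = f$slope, se = f$se_slope,
               p = f$wald_p_slope, aic = f$aic, n = f$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
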