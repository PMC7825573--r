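#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' positive case scores higher than a randomly chosen negative case, with
#' ties counted one half.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcomes (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stopf("auc: length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("auc: labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stopf("auc: degenerate outcomes (single class)")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# quantile bins of predicted risk, ties grouped; returns a factor
risk_bins <- function(probs, bins) {
  br <- unique(stats::quantile(probs, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) stopf("calibration: predicted risks are all identical")
  cut(probs, breaks = br, include.lowest = TRUE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `bins` quantile groups of predicted risk (ties
#' grouped, so fewer groups may result) and computes the Pearson-type
#' statistic \eqn{\chi^2 = \sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))} over
#' events and non-events, with `df = groups - 2` and an upper-tail p-value.
#' Groups with zero expected events or non-events trigger a rebinning with
#' one group fewer (with a notice). p-values below 0.05 indicate lack of
#' fit.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary outcomes (0/1).
#' @param bins requested number of risk groups (default 10, i.e. deciles).
#' @param quiet suppress rebinning notices.
#' @return An object of class `hl_test`: `chi2`, `df`, `p`, `bins` (the
#'   per-group table), `n_groups`.
#' @export
hosmer_lemeshow <- function(probs, labels, bins = 10, quiet = FALSE) {
  probs <- as.numeric(probs)
  labels <- as.numeric(labels)
  if (length(probs) != length(labels)) stopf("hosmer_lemeshow: length mismatch")
  if (any(probs <= 0) || any(probs >= 1)) {
    stopf("hosmer_lemeshow: probabilities must lie strictly in (0, 1)")
  }
  if (!all(labels %in% c(0, 1))) stopf("hosmer_lemeshow: labels must be binary")
  if (length(probs) < 2 * bins) {
    stopf("hosmer_lemeshow: need at least 2 observations per requested bin")
  }
  b <- bins
  repeat {
    g <- risk_bins(probs, b)
    n_g <- as.numeric(table(g))
    o1 <- as.numeric(tapply(labels, g, sum))
    e1 <- as.numeric(tapply(probs, g, sum))
    if (all(e1 > 1e-9) && all(n_g - e1 > 1e-9)) break
    if (b <= 2L) stopf("hosmer_lemeshow: cannot form groups with nonzero expected counts")
    b <- b - 1L
    if (!quiet) message(sprintf("hosmer_lemeshow: bins reduced to %d", b))
  }
  chi2 <- sum((o1 - e1)^2 / (e1 * (1 - e1 / n_g)))
  df <- length(n_g) - 2L
  p <- if (df >= 1L) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(
    list(chi2 = chi2, df = df, p = p,
         bins = data.frame(bin = seq_along(n_g), n = n_g, observed = o1,
                           expected = e1),
         n_groups = length(n_g)),
    class = "hl_test"
  )
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.4f on %d df, p = %.4g (%d groups)\n",
              x$chi2, x$df, x$p, x$n_groups))
  invisible(x)
}

#' Calibration curve data
#'
#' Per risk-group mean predicted probability, observed event rate and count,
#' for a predicted-vs-observed calibration plot.
#'
#' @inheritParams hosmer_lemeshow
#' @return Data frame with columns `bin`, `mean_pred`, `obs_rate`, `n`.
#' @export
calibration_curve <- function(probs, labels, bins = 10) {
  probs <- as.numeric(probs)
  labels <- as.numeric(labels)
  if (length(probs) != length(labels)) stopf("calibration_curve: length mismatch")
  if (!all(labels %in% c(0, 1))) stopf("calibration_curve: labels must be binary")
  g <- risk_bins(probs, bins)
  data.frame(
    bin = seq_len(nlevels(g)),
    mean_pred = as.numeric(tapply(probs, g, mean)),
    obs_rate = as.numeric(tapply(labels, g, mean)),
    n = as.numeric(table(g))
  )
}

#' Bootstrap internal validation of the univariate Vdose model
#'
#' TRIPOD type 1b internal validation: `B` resamples of the analysis subset
#' are drawn with replacement at the original size; on each resample the
#' univariate logistic model of the endpoint on the Vdose predictor is
#' refitted and its AUC computed. The headline figure is the median of the
#' B AUC values (the mean is also reported). Resamples with a single
#' outcome class are redrawn (counted); if redraws outnumber the kept
#' resamples the cohort is declared too unstable to validate. The default
#' per-resample AUC is apparent (fit and scored on the same resample); the
#' Harrell variant additionally scores each resample model on the original
#' data and reports an optimism-corrected AUC.
#'
#' Calibration of the full-data fit is assessed with [hosmer_lemeshow()]
#' and [calibration_curve()].
#'
#' @param cohort a `dvh_cohort`.
#' @param predictor_dose_gy dose defining the Vdose predictor (Gy).
#' @param rule an [outcome_rule()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed (reproducible given the seed).
#' @param method `"apparent"` (default) or `"harrell"`.
#' @param hl_bins risk groups for the Hosmer-Lemeshow test.
#' @return An object of class `validation_report`: `auc_apparent`,
#'   `auc_median`, `auc_mean`, `auc_distribution` (length B),
#'   `auc_optimism_corrected` (Harrell method only), `hl` ([hosmer_lemeshow()]
#'   result), `calibration_bins`, `B`, `seed`, `redraws`, `n`, `method`.
#' @export
bootstrap_validate <- function(cohort, predictor_dose_gy = 51.43,
                               rule = outcome_rule(2), B = 1000, seed = 1,
                               method = c("apparent", "harrell"),
                               hl_bins = 10) {
  method <- match.arg(method)
  if (B < 1) stopf("bootstrap_validate: B must be at least 1")
  cohort <- as_cohort(cohort)
  sub <- apply_outcome_rule(cohort, rule)
  y <- sub$y
  x <- cohort_vdose(cohort[sub$keep], predictor_dose_gy)
  n <- length(y)

  full_fit <- fit_logistic_univariate(x, y)
  p_full <- stats::plogis(full_fit$intercept + full_fit$slope * x)
  auc_app <- auc(p_full, y)
  hl <- hosmer_lemeshow(p_full, y, bins = hl_bins, quiet = TRUE)
  calib <- calibration_curve(p_full, y, bins = hl_bins)

  aucs <- numeric(B)
  optimism <- numeric(B)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L &&
            diff(range(x[idx])) > 1e-12) break
        redraws <- redraws + 1L
        if (redraws > B) {
          stopf("bootstrap_validate: unstable cohort (more than %d degenerate resamples)", B)
        }
      }
      fb <- fit_logistic_univariate(x[idx], y[idx])
      pb <- stats::plogis(fb$intercept + fb$slope * x[idx])
      aucs[b] <- auc(pb, y[idx])
      if (method == "harrell") {
        p_orig <- stats::plogis(fb$intercept + fb$slope * x)
        optimism[b] <- aucs[b] - auc(p_orig, y)
      }
    }
  })

  structure(
    list(auc_apparent = auc_app,
         auc_median = stats::median(aucs),
         auc_mean = mean(aucs),
         auc_distribution = aucs,
         auc_optimism_corrected = if (method == "harrell")
           auc_app - mean(optimism) else NA_real_,
         hl = hl, calibration_bins = calib,
         B = B, seed = seed, redraws = redraws, n = n, method = method,
         predictor_dose_gy = predictor_dose_gy, fit = full_fit),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Bootstrap internal validation (B = %d, seed = %d, n = %d, %s)\n",
    x$B, x$seed, x$n, x$method))
  cat(sprintf("  AUC: apparent %.3f, bootstrap median %.3f, mean %.3f\n",
              x$auc_apparent, x$auc_median, x$auc_mean))
  if (!is.na(x$auc_optimism_corrected)) {
    cat(sprintf("  optimism-corrected AUC: %.3f\n", x$auc_optimism_corrected))
  }
  cat(sprintf("  Hosmer-Lemeshow: chi2 = %.3f on %d df, p = %.4g\n",
              x$hl$chi2, x$hl$df, x$hl$p))
  invisible(x)
}

#' Serialize a validation report
#'
#' Writes the headline numbers as JSON and the calibration bins as CSV.
#'
#' @param report a `validation_report`.
#' @param json_file,calibration_file output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_validation_report <- function(report, json_file = NULL,
                                    calibration_file = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (!is.null(json_file)) {
    jsonlite::write_json(
      list(auc_apparent = report$auc_apparent,
           auc_median = report$auc_median,
           auc_mean = report$auc_mean,
           B = report$B, seed = report$seed,
           hl_chi2 = report$hl$chi2, hl_df = report$hl$df, hl_p = report$hl$p),
      json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(calibration_file)) {
    utils::write.csv(report$calibration_bins, calibration_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(c(json = json_file, calibration = calibration_file))
}
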