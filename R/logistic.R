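#' Logistic dose-volume risk model
#'
#' The published final model for late grade >= 2 genitourinary toxicity:
#' \deqn{P = \frac{e^{a + bX}}{1 + e^{a + bX}},}
#' where X is the fraction of bladder volume inside the isodose at
#' `predictor_dose_gy`. Defaults are the reported coefficients a = -2.5,
#' b = 4.3 with predictor dose 51.43 Gy. X is a fraction in \[0, 1\], not a
#' percent: with these coefficients the published risk thresholds are only
#' reproduced on the fraction scale.
#'
#' @param intercept intercept a.
#' @param slope slope b on the volume fraction.
#' @param predictor_dose_gy dose level defining the Vdose predictor (Gy).
#' @return An object of class `logistic_risk_model`.
#' @export
logistic_risk_model <- function(intercept = -2.5, slope = 4.3,
                                predictor_dose_gy = 51.43) {
  if (!is.finite(intercept) || !is.finite(slope)) {
    stopf("logistic_risk_model: coefficients must be finite")
  }
  if (!is.finite(predictor_dose_gy) || predictor_dose_gy <= 0) {
    stopf("logistic_risk_model: predictor dose must be positive")
  }
  structure(
    list(intercept = intercept, slope = slope,
         predictor_dose_gy = predictor_dose_gy),
    class = "logistic_risk_model"
  )
}

#' @export
print.logistic_risk_model <- function(x, ...) {
  cat(sprintf(
    "Logistic risk model on V%.4g: P = plogis(%.4g + %.4g * X), X = volume fraction\n",
    x$predictor_dose_gy, x$intercept, x$slope))
  invisible(x)
}

#' Evaluate the logistic risk model
#'
#' @param x bladder volume fraction(s) in \[0, 1\].
#' @param model a [logistic_risk_model()].
#' @return Toxicity probability in (0, 1).
#' @examples
#' m <- logistic_risk_model()
#' logistic_risk(0, m)     # sigma(-2.5) ~ 0.076
#' logistic_risk(0.59, m)  # ~ 0.51
#' @export
logistic_risk <- function(x, model = logistic_risk_model()) {
  stopifnot(inherits(model, "logistic_risk_model"))
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stopf("logistic_risk: volume fraction must lie in [0, 1]")
  }
  stats::plogis(model$intercept + model$slope * x)
}

#' Univariate logistic regression fit
#'
#' Maximum-likelihood fit of `y ~ x` (binomial family, IRLS via
#' [stats::glm()]) with Wald standard errors, a two-sided Wald p-value for
#' the slope, the log-likelihood and AIC = 4 - 2 logLik (two parameters).
#' Complete separation or IRLS non-convergence is flagged through
#' `converged = FALSE` rather than raised; the Wald p-value is unreliable in
#' that case.
#'
#' @param x numeric predictor (non-constant).
#' @param y binary outcome, both classes present.
#' @return An object of class `logistic_fit`: `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `wald_p_slope`, `loglik`, `aic`, `n`,
#'   `converged`.
#' @export
fit_logistic_univariate <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stopf("fit_logistic_univariate: length mismatch")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (!all(y %in% c(0, 1))) {
    stopf("fit_logistic_univariate: outcomes must be binary 0/1")
  }
  if (length(unique(y)) < 2L) {
    stopf("fit_logistic_univariate: degenerate outcomes (single class)")
  }
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    stopf("fit_logistic_univariate: collinear predictor (constant x)")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::summary.glm(fit)$coefficients
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(intercept = cf[1, 1], slope = cf[2, 1],
         se_intercept = cf[1, 2], se_slope = cf[2, 2],
         wald_p_slope = cf[2, 4],
         loglik = ll, aic = 4 - 2 * ll, n = length(y),
         converged = isTRUE(fit$converged) && !separated),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Univariate logistic fit (n = %d%s):\n  intercept %.4f (SE %.4f), slope %.4f (SE %.4f), Wald p = %.4g\n  logLik = %.3f, AIC = %.3f\n",
    x$n, if (x$converged) "" else ", separation/non-convergence flagged",
    x$intercept, x$se_intercept, x$slope, x$se_slope, x$wald_p_slope,
    x$loglik, x$aic))
  invisible(x)
}
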