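#' Generalized equivalent uniform dose (gEUD)
#'
#' The gEUD is the power mean of the bin doses of a differential DVH,
#' \deqn{EUD = \left(\sum_i v_i D_i^a\right)^{1/a},}
#' the uniform dose estimated to carry the same complication probability as
#' the inhomogeneous distribution. The volume exponent `a` is
#' structure-specific; the bladder value used throughout is 1.4. `a = 1`
#' gives the mean dose; large positive `a` approaches the maximum dose,
#' large negative `a` the minimum.
#'
#' @param ddvh a [differential_dvh()] (a [dvh_curve()] is converted first).
#' @param a volume-effect exponent, non-zero. Default 1.4 (bladder).
#' @return EUD in Gy, between the minimum and maximum bin dose.
#' @examples
#' d <- differential_dvh(c(40, 60), c(0.5, 0.5))
#' compute_eud(d, a = 1)    # 50, the mean dose
#' compute_eud(d, a = 1.4)
#' @export
compute_eud <- function(ddvh, a = 1.4) {
  if (inherits(ddvh, "dvh_curve")) ddvh <- cumulative_to_differential(ddvh)
  stopifnot(inherits(ddvh, "dvh_diff"))
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a == 0) {
    stopf("compute_eud: exponent a must be a non-zero number")
  }
  keep <- ddvh$v > 0
  v <- ddvh$v[keep]
  d <- ddvh$bin_center_gy[keep]
  if (length(v) == 0L) stopf("compute_eud: differential DVH has no mass")
  if (any(d < 0)) stopf("compute_eud: negative bin dose")
  if (any(d == 0)) {
    if (a < 0) return(0)
    v <- v[d > 0]
    d <- d[d > 0]
    if (length(v) == 0L) return(0)
  }
  # power mean in log space: stable for |a| up to the +/-50 limit checks
  exp(logsumexp(log(v) + a * log(d)) / a)
}

#' Logistic NTCP dose-response model
#'
#' Normal tissue complication probability as a function of EUD,
#' \deqn{NTCP = \frac{1}{1 + (TD_{50}/EUD)^{4\gamma_{50}}},}
#' where `td50` is the uniform dose giving a 50% complication rate and
#' `gamma50` the normalized slope of the sigmoid at that point
#' (\eqn{\gamma_{50} = TD_{50}\,|dNTCP/dD|} at \eqn{D = TD_{50}}).
#'
#' @param td50 tolerance dose for 50% complications (Gy), positive.
#' @param gamma50 normalized slope at TD50, positive.
#' @return An object of class `ntcp_model`.
#' @export
ntcp_model <- function(td50, gamma50) {
  if (!is.numeric(td50) || length(td50) != 1L || is.na(td50) || td50 <= 0) {
    stopf("ntcp_model: td50 must be a positive dose in Gy")
  }
  if (!is.numeric(gamma50) || length(gamma50) != 1L || is.na(gamma50) ||
      gamma50 <= 0) {
    stopf("ntcp_model: gamma50 must be positive")
  }
  structure(list(td50 = td50, gamma50 = gamma50), class = "ntcp_model")
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat(sprintf("Logistic NTCP model: TD50 = %.4g Gy, gamma50 = %.4g\n",
              x$td50, x$gamma50))
  invisible(x)
}

#' Evaluate the NTCP model
#'
#' @param eud EUD in Gy (positive; vectorized).
#' @param model an [ntcp_model()].
#' @return Complication probability in (0, 1); 0.5 exactly at `eud = td50`.
#' @export
ntcp <- function(eud, model) {
  stopifnot(inherits(model, "ntcp_model"))
  eud <- as.numeric(eud)
  if (anyNA(eud) || any(eud <= 0)) stopf("ntcp: eud must be positive")
  1 / (1 + (model$td50 / eud)^(4 * model$gamma50))
}

#' Invert the NTCP model
#'
#' The EUD at which the model predicts complication probability `p`:
#' \eqn{EUD = TD_{50} / ((1-p)/p)^{1/(4\gamma_{50})}}.
#'
#' @param p probability in (0, 1); vectorized.
#' @param model an [ntcp_model()].
#' @return EUD in Gy.
#' @export
invert_ntcp <- function(p, model) {
  stopifnot(inherits(model, "ntcp_model"))
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stopf("invert_ntcp: p must lie strictly between 0 and 1")
  }
  model$td50 / ((1 - p) / p)^(1 / (4 * model$gamma50))
}

#' Check the gamma50 slope identity numerically
#'
#' gamma50 is defined as TD50 times the absolute NTCP slope at TD50. This
#' recomputes it by central finite difference (step `1e-4 * td50`) as a
#' consistency check on the model parameterization.
#'
#' @param model an [ntcp_model()].
#' @return The numerically estimated gamma50 (equals `model$gamma50` to
#'   about 1e-6 relative).
#' @export
gamma50_check <- function(model) {
  stopifnot(inherits(model, "ntcp_model"))
  h <- 1e-4 * model$td50
  slope <- (ntcp(model$td50 + h, model) - ntcp(model$td50 - h, model)) / (2 * h)
  model$td50 * abs(slope)
}

#' Maximum-likelihood fit of the NTCP model
#'
#' Fits `td50` and `gamma50` by maximizing the Bernoulli log-likelihood with
#' \eqn{p_i = NTCP(EUD_i)}. Optimization is unconstrained on
#' `(log td50, log gamma50)` (Nelder-Mead, relative tolerance 1e-10), so the
#' positivity constraints hold by construction. Non-convergence is flagged,
#' not raised.
#'
#' @param euds per-patient EUD values (Gy).
#' @param outcomes binary outcomes (0/1), same length.
#' @param init optional starting `c(td50, gamma50)`; defaults to the median
#'   EUD and 1.
#' @return An object of class `ntcp_fit`: fields `model` ([ntcp_model()]),
#'   `loglik`, `aic`, `converged`, `n`.
#' @export
fit_ntcp <- function(euds, outcomes, init = NULL) {
  euds <- as.numeric(euds)
  y <- as.numeric(outcomes)
  if (length(euds) != length(y)) stopf("fit_ntcp: length mismatch")
  keep <- !is.na(euds) & !is.na(y)
  euds <- euds[keep]
  y <- y[keep]
  if (any(euds <= 0)) stopf("fit_ntcp: EUD values must be positive")
  if (!all(y %in% c(0, 1))) stopf("fit_ntcp: outcomes must be binary")
  if (length(unique(y)) < 2L) {
    stopf("fit_ntcp: degenerate outcomes (single class)")
  }
  if (is.null(init)) init <- c(stats::median(euds), 1)
  nll <- function(par) {
    td50 <- exp(par[1])
    g <- exp(par[2])
    p <- 1 / (1 + (td50 / euds)^(4 * g))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  opt <- stats::optim(log(init), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 5000))
  structure(
    list(model = ntcp_model(exp(opt$par[1]), exp(opt$par[2])),
         loglik = -opt$value, aic = 2 * 2 + 2 * opt$value,
         converged = opt$convergence == 0L, n = length(y)),
    class = "ntcp_fit"
  )
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat(sprintf(
    "NTCP fit (n = %d%s): TD50 = %.2f Gy, gamma50 = %.3f, logLik = %.3f, AIC = %.2f\n",
    x$n, if (x$converged) "" else ", NOT converged",
    x$model$td50, x$model$gamma50, x$loglik, x$aic))
  invisible(x)
}
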