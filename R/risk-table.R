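#' Volume threshold for a given toxicity risk
#'
#' Algebraic inversion of the logistic risk model: the volume fraction at
#' which the predicted risk equals `risk`,
#' \eqn{X^* = (\mathrm{logit}(risk) - a) / b}. Values outside \[0, 1\]
#' (risks unreachable for any physical volume) are returned unclamped with
#' attribute `unreachable = TRUE`.
#'
#' @param risk probability strictly in (0, 1); vectorized.
#' @param model a [logistic_risk_model()] with non-zero slope.
#' @return Volume fraction(s); attribute `unreachable` is a logical vector.
#' @examples
#' volume_for_risk(0.5, logistic_risk_model())  # 0.5814 -> "V51 < 58.1%"
#' @export
volume_for_risk <- function(risk, model = logistic_risk_model()) {
  stopifnot(inherits(model, "logistic_risk_model"))
  risk <- as.numeric(risk)
  if (anyNA(risk) || any(risk <= 0) || any(risk >= 1)) {
    stopf("volume_for_risk: risk must lie strictly between 0 and 1")
  }
  if (model$slope == 0) {
    stopf("volume_for_risk: model slope is zero, risk does not depend on volume")
  }
  x <- (stats::qlogis(risk) - model$intercept) / model$slope
  attr(x, "unreachable") <- x < 0 | x > 1
  x
}

#' Dose-volume constraint table from a logistic risk model
#'
#' Inverts the model at each requested risk level to produce clinician-facing
#' constraints of the form "keep V(dose) below X% to keep the toxicity risk
#' below r%". Percentages are rendered half-up at one decimal; the
#' unrounded fraction is kept alongside so the inversion round-trips
#' exactly.
#'
#' @param model a [logistic_risk_model()].
#' @param levels strictly increasing risk levels in (0, 1);
#'   default `c(0.10, 0.20, 0.50)`.
#' @return An object of classes `risk_table`/`data.frame` with columns
#'   `risk_level`, `risk_percent`, `v_fraction`, `v_percent`, `unreachable`.
#' @export
build_risk_table <- function(model = logistic_risk_model(),
                             levels = c(0.10, 0.20, 0.50)) {
  stopifnot(inherits(model, "logistic_risk_model"))
  levels <- as.numeric(levels)
  if (length(levels) == 0L) {
    out <- data.frame(risk_level = numeric(0), risk_percent = numeric(0),
                      v_fraction = numeric(0), v_percent = numeric(0),
                      unreachable = logical(0))
    return(structure(out, class = c("risk_table", "data.frame"), model = model))
  }
  if (any(levels <= 0) || any(levels >= 1) || any(diff(levels) <= 0)) {
    stopf("build_risk_table: levels must be strictly increasing in (0, 1)")
  }
  v <- volume_for_risk(levels, model)
  out <- data.frame(
    risk_level = levels,
    risk_percent = round_half_up(levels * 100, 1),
    v_fraction = as.numeric(v),
    v_percent = round_half_up(as.numeric(v) * 100, 1),
    unreachable = attr(v, "unreachable")
  )
  structure(out, class = c("risk_table", "data.frame"), model = model)
}

#' @export
print.risk_table <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("Risk of toxicity related to V%.4g (%%)\n", m$predictor_dose_gy))
  cat(sprintf("%-18s %s\n", sprintf("V%.4g volume (%%)", m$predictor_dose_gy),
              "Risk"))
  for (i in seq_len(nrow(x))) {
    flag <- if (x$unreachable[i]) "  [unreachable]" else ""
    cat(sprintf("<%-17s <%s%%%s\n", sprintf("%.1f%%", x$v_percent[i]),
                format(x$risk_percent[i]), flag))
  }
  invisible(x)
}

#' Write a risk table to CSV
#'
#' Columns `risk_percent`, `v_percent`, `unreachable`; decimal point,
#' fixed column order, locale-independent.
#'
#' @param x a `risk_table`.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_risk_table <- function(x, file) {
  stopifnot(inherits(x, "risk_table"))
  df <- data.frame(risk_percent = x$risk_percent, v_percent = x$v_percent,
                   unreachable = x$unreachable)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Predicted toxicity risk for one patient
#'
#' Evaluates the logistic risk model at the patient's volume fraction inside
#' the predictor isodose.
#'
#' @param record a [patient_record()].
#' @param model a [logistic_risk_model()].
#' @return Probability in (0, 1).
#' @export
patient_risk <- function(record, model = logistic_risk_model()) {
  stopifnot(inherits(record, "patient_record"))
  logistic_risk(volume_at_dose(record$dvh, model$predictor_dose_gy), model)
}
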