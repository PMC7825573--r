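#' Cumulative dose-volume histogram for one patient
#'
#' A cumulative DVH gives, for each dose level, the fraction of the organ
#' volume receiving at least that dose. Internally all volumes are fractions
#' in \[0, 1\]; readers convert percent and absolute (cc) volumes. Curves
#' whose grid does not start at 0 Gy are left-extended with volume 1 there
#' (the whole organ receives at least 0 Gy).
#'
#' @param patient_id character scalar identifying the patient.
#' @param dose_gy strictly increasing non-negative dose grid (Gy).
#' @param cum_volume non-increasing volume at each grid dose. Interpreted as
#'   a fraction after normalization.
#' @param total_volume_cc optional positive organ volume (cm^3), recorded
#'   when the source data were absolute volumes.
#' @param normalize divide `cum_volume` by its first value so the curve
#'   starts at exactly 1. Default `TRUE`.
#' @return An object of class `dvh_curve` with fields `patient_id`,
#'   `dose_gy`, `cum_volume`, `total_volume_cc`.
#' @examples
#' c1 <- dvh_curve("p1", c(0, 40, 80), c(1, 0.4, 0))
#' volume_at_dose(c1, 51.43)
#' @export
dvh_curve <- function(patient_id, dose_gy, cum_volume, total_volume_cc = NULL,
                      normalize = TRUE) {
  patient_id <- as.character(patient_id)[1]
  dose_gy <- as.numeric(dose_gy)
  cum_volume <- as.numeric(cum_volume)
  if (length(dose_gy) != length(cum_volume)) {
    stopf("DVH for patient '%s': dose and volume lengths differ", patient_id)
  }
  if (length(dose_gy) < 1L || anyNA(dose_gy) || anyNA(cum_volume)) {
    stopf("DVH for patient '%s': empty grid or missing values", patient_id)
  }
  if (any(dose_gy < 0)) {
    stopf("malformed DVH for patient '%s': negative dose", patient_id)
  }
  if (any(diff(dose_gy) <= 0)) {
    stopf("malformed DVH for patient '%s': dose grid not strictly increasing",
          patient_id)
  }
  if (normalize) {
    if (cum_volume[1] <= 0) {
      stopf("malformed DVH for patient '%s': zero volume at lowest dose",
            patient_id)
    }
    cum_volume <- cum_volume / cum_volume[1]
  }
  if (dose_gy[1] > 0) {
    dose_gy <- c(0, dose_gy)
    cum_volume <- c(1, cum_volume)
  }
  obj <- structure(
    list(patient_id = patient_id, dose_gy = dose_gy, cum_volume = cum_volume,
         total_volume_cc = total_volume_cc),
    class = "dvh_curve"
  )
  validate_dvh_curve(obj)
  obj
}

validate_dvh_curve <- function(x, tol = 1e-9) {
  id <- x$patient_id
  if (abs(x$cum_volume[1] - 1) > tol) {
    stopf("malformed DVH for patient '%s': volume at 0 Gy is %.6g, not 1",
          id, x$cum_volume[1])
  }
  if (any(diff(x$cum_volume) > tol)) {
    stopf("malformed DVH for patient '%s': cumulative volume increases with dose",
          id)
  }
  if (any(x$cum_volume < -tol) || any(x$cum_volume > 1 + tol)) {
    stopf("malformed DVH for patient '%s': volume outside [0, 1]", id)
  }
  if (!is.null(x$total_volume_cc) &&
      (!is.numeric(x$total_volume_cc) || x$total_volume_cc <= 0)) {
    stopf("DVH for patient '%s': total volume must be positive", id)
  }
  invisible(x)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "Cumulative DVH for patient '%s': %d grid points, 0-%.4g Gy%s\n",
    x$patient_id, length(x$dose_gy), max(x$dose_gy),
    if (is.null(x$total_volume_cc)) "" else
      sprintf(", organ volume %.4g cc", x$total_volume_cc)
  ))
  invisible(x)
}

#' Differential dose-volume histogram
#'
#' Bin representation of a dose distribution: `v` holds the fraction of the
#' organ in each dose bin (summing to 1), `bin_center_gy` the bin-center
#' doses. Produced from a cumulative curve by [cumulative_to_differential()],
#' which also records the originating grid so the conversion is invertible.
#'
#' @param bin_center_gy ascending bin-center doses (Gy).
#' @param v non-negative volume fraction per bin; must sum to 1 within 1e-9.
#' @param dose_edges optional originating cumulative grid (used by
#'   [differential_to_cumulative()] for an exact round trip).
#' @param patient_id optional identifier carried through conversions.
#' @return An object of class `dvh_diff`.
#' @export
differential_dvh <- function(bin_center_gy, v, dose_edges = NULL,
                             patient_id = NA_character_) {
  bin_center_gy <- as.numeric(bin_center_gy)
  v <- as.numeric(v)
  if (length(v) != length(bin_center_gy) || length(v) == 0L) {
    stopf("differential DVH: bins and volumes must be non-empty and equal length")
  }
  if (any(v < -1e-12)) stopf("differential DVH: negative bin volume")
  v <- pmax(v, 0)
  if (abs(sum(v) - 1) > 1e-9) {
    stopf("differential DVH: bin volumes sum to %.12g, not 1", sum(v))
  }
  if (any(diff(bin_center_gy) < 0)) {
    stopf("differential DVH: bin centers must be ascending")
  }
  structure(
    list(bin_center_gy = bin_center_gy, v = v, dose_edges = dose_edges,
         patient_id = patient_id),
    class = "dvh_diff"
  )
}

#' @export
print.dvh_diff <- function(x, ...) {
  cat(sprintf("Differential DVH: %d bins, centers %.4g-%.4g Gy\n",
              length(x$v), min(x$bin_center_gy), max(x$bin_center_gy)))
  invisible(x)
}

#' Convert a cumulative DVH to differential form
#'
#' Interior bin volumes are successive differences of the cumulative curve,
#' with bin centers at grid midpoints; any residual volume still covered at
#' the maximum grid dose is absorbed into a final bin located there.
#'
#' @param curve a [dvh_curve()].
#' @param residual_tol residual cumulative volume at the grid maximum below
#'   which no final bin is added.
#' @return A [differential_dvh()] whose bin volumes sum to 1.
#' @export
cumulative_to_differential <- function(curve, residual_tol = 1e-12) {
  stopifnot(inherits(curve, "dvh_curve"))
  d <- curve$dose_gy
  cv <- curve$cum_volume
  n <- length(d)
  if (n < 2L) {
    stopf("DVH for patient '%s': need at least 2 grid points to form bins",
          curve$patient_id)
  }
  v <- -diff(cv)
  centers <- (d[-n] + d[-1]) / 2
  if (cv[n] > residual_tol) {
    v <- c(v, cv[n])
    centers <- c(centers, d[n])
  }
  differential_dvh(centers, v, dose_edges = d, patient_id = curve$patient_id)
}

#' Convert a differential DVH back to cumulative form
#'
#' Inverse of [cumulative_to_differential()]: when the differential object
#' carries its originating grid the cumulative curve is reproduced exactly at
#' the grid points; otherwise a step curve dropping after each bin center is
#' built.
#'
#' @param ddvh a [differential_dvh()].
#' @return A [dvh_curve()].
#' @export
differential_to_cumulative <- function(ddvh) {
  stopifnot(inherits(ddvh, "dvh_diff"))
  if (any(ddvh$v < 0)) stopf("differential DVH: negative bin volume")
  id <- if (is.na(ddvh$patient_id)) "ddvh" else ddvh$patient_id
  if (!is.null(ddvh$dose_edges)) {
    d <- ddvh$dose_edges
    k <- length(d)
    cv <- c(1, 1 - cumsum(ddvh$v[seq_len(k - 1L)]))
  } else {
    if (ddvh$bin_center_gy[1] <= 0) {
      stopf("differential DVH: bin centers must be positive to rebuild a grid")
    }
    d <- c(0, ddvh$bin_center_gy)
    cv <- c(1, 1 - cumsum(ddvh$v))
  }
  cv <- pmin(pmax(cv, 0), 1)
  dvh_curve(id, d, cv, normalize = FALSE)
}

#' Volume fraction receiving at least a given dose (Vdose)
#'
#' Linear interpolation of the cumulative curve at `dose`; beyond the grid
#' maximum the covered volume is 0. This is the dosimetric predictor the
#' Vdose scan and the risk model are built on (e.g. V51.43).
#'
#' @param curve a [dvh_curve()].
#' @param dose non-negative dose (Gy); vectorized.
#' @return Volume fraction(s) in \[0, 1\].
#' @export
volume_at_dose <- function(curve, dose) {
  stopifnot(inherits(curve, "dvh_curve"))
  dose <- as.numeric(dose)
  if (anyNA(dose) || any(dose < 0)) {
    stopf("volume_at_dose: dose must be non-negative")
  }
  stats::approx(curve$dose_gy, curve$cum_volume, xout = dose,
                yleft = 1, yright = 0, ties = "ordered")$y
}

#' Mean organ dose from a cumulative DVH
#'
#' The volume-weighted mean of the bin doses, i.e. the gEUD with volume
#' exponent 1.
#'
#' @param x a [dvh_curve()] or a patient record.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  if (inherits(x, "patient_record")) x <- x$dvh
  compute_eud(cumulative_to_differential(x), a = 1)
}

#' Patient record: DVH plus graded outcome
#'
#' @param patient_id character scalar.
#' @param dvh a [dvh_curve()].
#' @param grade integer late-toxicity grade in 0..4 (RTOG/CTCAE).
#' @param covariates optional named list of scalar covariates (`age`, `psa`,
#'   `gleason_group`, `prescribed_dose_gy`).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, dvh, grade, covariates = NULL) {
  stopifnot(inherits(dvh, "dvh_curve"))
  grade <- as.integer(grade)
  if (length(grade) != 1L || is.na(grade) || !grade %in% 0:4) {
    stopf("patient '%s': toxicity grade must be an integer in 0..4",
          as.character(patient_id))
  }
  structure(
    list(patient_id = as.character(patient_id)[1], dvh = dvh, grade = grade,
         covariates = covariates),
    class = "patient_record"
  )
}

#' Assemble patient records into a cohort
#'
#' @param records list of [patient_record()] objects.
#' @return An object of class `dvh_cohort` (a list of records).
#' @export
as_cohort <- function(records) {
  if (inherits(records, "dvh_cohort")) return(records)
  ok <- vapply(records, inherits, logical(1), what = "patient_record")
  if (length(records) == 0L || !all(ok)) {
    stopf("as_cohort: expected a non-empty list of patient_record objects")
  }
  structure(records, class = "dvh_cohort")
}

#' @export
`[.dvh_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "dvh_cohort")
}

#' @export
print.dvh_cohort <- function(x, ...) {
  g <- grades(x)
  cat(sprintf("DVH cohort: %d patients; grade counts 0-4: %s\n",
              length(x), paste(tabulate(g + 1L, 5L), collapse = "/")))
  invisible(x)
}

#' Toxicity grades of a cohort
#' @param cohort a `dvh_cohort`.
#' @return Integer vector of grades.
#' @export
grades <- function(cohort) {
  vapply(cohort, function(r) r$grade, integer(1))
}

#' Vdose values across a cohort
#'
#' @param cohort a `dvh_cohort`.
#' @param dose dose level(s) in Gy.
#' @return If `dose` is scalar, a vector (one value per patient); otherwise a
#'   patients-by-doses matrix.
#' @export
cohort_vdose <- function(cohort, dose) {
  m <- t(vapply(cohort, function(r) volume_at_dose(r$dvh, dose),
                numeric(length(dose))))
  if (length(dose) == 1L) as.numeric(m) else m
}
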