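#' Read a DVH cohort from CSV files
#'
#' Reads the long-form DVH dialect (columns `patient_id`, `dose_gy`,
#' `volume`, `volume_unit` with unit `fraction`, `percent` or `cc`) and an
#' outcome table (columns `patient_id`, `grade`, optionally `age`, `psa`,
#' `gleason_group`, `prescribed_dose_gy`). Volumes are normalized to
#' fractions of the organ volume; every patient with a DVH must have an
#' outcome row.
#'
#' @param dvh_file path to the long-form DVH CSV.
#' @param outcome_file path to the outcome CSV.
#' @return A `dvh_cohort`, one [patient_record()] per patient present in the
#'   DVH file.
#' @seealso [write_cohort()] for the emitting counterpart.
#' @export
read_cohort <- function(dvh_file, outcome_file) {
  dvh <- utils::read.csv(dvh_file, stringsAsFactors = FALSE)
  need <- c("patient_id", "dose_gy", "volume", "volume_unit")
  if (!all(need %in% names(dvh))) {
    stopf("DVH file '%s': expected columns %s", dvh_file,
          paste(need, collapse = ", "))
  }
  out <- utils::read.csv(outcome_file, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "grade") %in% names(out))) {
    stopf("outcome file '%s': expected columns patient_id, grade", outcome_file)
  }
  out$patient_id <- as.character(out$patient_id)
  dvh$patient_id <- as.character(dvh$patient_id)
  if (anyDuplicated(out$patient_id)) {
    stopf("outcome file '%s': duplicated patient ids", outcome_file)
  }

  dvh_ids <- unique(dvh$patient_id)
  missing_out <- setdiff(dvh_ids, out$patient_id)
  if (length(missing_out) > 0L) {
    stopf("patients with a DVH but no outcome row: %s",
          paste(missing_out, collapse = ", "))
  }
  bad_grade <- !(out$grade %in% 0:4)
  if (any(bad_grade)) {
    stopf("grades outside 0..4 for patient(s): %s",
          paste(out$patient_id[bad_grade], collapse = ", "))
  }

  cov_cols <- intersect(c("age", "psa", "gleason_group", "prescribed_dose_gy"),
                        names(out))
  records <- lapply(dvh_ids, function(id) {
    rows <- dvh[dvh$patient_id == id, , drop = FALSE]
    unit <- unique(rows$volume_unit)
    if (length(unit) != 1L || !unit %in% c("fraction", "percent", "cc")) {
      stopf("patient '%s': volume_unit must be one of fraction/percent/cc and consistent",
            id)
    }
    vol <- rows$volume
    total_cc <- NULL
    if (unit == "percent") {
      vol <- vol / 100
    } else if (unit == "cc") {
      total_cc <- max(vol)
      vol <- vol / total_cc
    }
    # dvh_curve() rejects non-monotone grids, naming the patient
    curve <- dvh_curve(id, rows$dose_gy, vol, total_volume_cc = total_cc)
    orow <- out[match(id, out$patient_id), , drop = FALSE]
    covs <- NULL
    if (length(cov_cols) > 0L) {
      covs <- as.list(orow[, cov_cols, drop = FALSE])
      covs <- lapply(covs, as.numeric)
    }
    patient_record(id, curve, orow$grade, covariates = covs)
  })
  as_cohort(records)
}

#' Write a DVH cohort to CSV files
#'
#' Emits the same dialects [read_cohort()] consumes, with bit-stable
#' ordering: patients sorted by id, doses ascending within patient.
#'
#' @param cohort a `dvh_cohort`.
#' @param dvh_file,outcome_file output paths.
#' @param volume_unit unit to write volumes in (`fraction`, `percent`, `cc`;
#'   `cc` requires `total_volume_cc` on every curve).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, dvh_file, outcome_file,
                         volume_unit = c("fraction", "percent", "cc")) {
  cohort <- as_cohort(cohort)
  volume_unit <- match.arg(volume_unit)
  ids <- vapply(cohort, function(r) r$patient_id, character(1))
  ord <- order(ids)

  dvh_rows <- do.call(rbind, lapply(cohort[ord], function(r) {
    vol <- r$dvh$cum_volume
    if (volume_unit == "percent") {
      vol <- vol * 100
    } else if (volume_unit == "cc") {
      if (is.null(r$dvh$total_volume_cc)) {
        stopf("patient '%s': no total volume recorded, cannot write cc",
              r$patient_id)
      }
      vol <- vol * r$dvh$total_volume_cc
    }
    data.frame(patient_id = r$patient_id, dose_gy = r$dvh$dose_gy,
               volume = vol, volume_unit = volume_unit,
               stringsAsFactors = FALSE)
  }))

  cov_names <- unique(unlist(lapply(cohort, function(r) names(r$covariates))))
  out_rows <- do.call(rbind, lapply(cohort[ord], function(r) {
    row <- data.frame(patient_id = r$patient_id, grade = r$grade,
                      stringsAsFactors = FALSE)
    for (nm in cov_names) {
      v <- r$covariates[[nm]]
      row[[nm]] <- if (is.null(v)) NA_real_ else as.numeric(v)
    }
    row
  }))

  utils::write.csv(dvh_rows, dvh_file, row.names = FALSE, quote = FALSE)
  utils::write.csv(out_rows, outcome_file, row.names = FALSE, quote = FALSE)
  invisible(c(dvh = dvh_file, outcome = outcome_file))
}
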