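# Cohort CSV interchange. Two files: patients.csv and fractures.csv, UTF-8
# with a header row; flags as 0/1; side accepts left/right and the L/R
# aliases. Percent positions are written with full double precision so a
# write/read round trip is lossless.

#' Read a cohort from patients.csv / fractures.csv
#'
#' @param patients_path Path to the patient-level CSV (`patient_id`, and
#'   optionally `age`, `sex`, `mechanism`, `clavicle`, `scapula`,
#'   `thoracic_vertebra`, `sternum` as 0/1).
#' @param fractures_path Path to the fracture-line CSV (`patient_id`,
#'   `rib`, `side`, and `percent` and/or `d1`,`d2`).
#' @param ... Passed to [validate_cohort()] (sector boundaries, bin
#'   width).
#' @return A `rib_cohort`. A fractures file containing only the header is
#'   accepted with a warning (a cohort with zero fracture lines).
#' @export
read_cohort_csv <- function(patients_path, fractures_path, ...) {
  patients <- utils::read.csv(patients_path, stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  fractures <- utils::read.csv(fractures_path, stringsAsFactors = FALSE,
                               colClasses = c(patient_id = "character"))
  if (nrow(fractures) == 0L) {
    warning("fractures file contains no records: ", fractures_path,
            call. = FALSE)
  }
  validate_cohort(patients, fractures, ...)
}

#' Write a cohort to patients.csv / fractures.csv
#'
#' @param cohort A `rib_cohort`.
#' @param patients_path,fractures_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort_csv <- function(cohort, patients_path, fractures_path) {
  stopifnot(inherits(cohort, "rib_cohort"))
  pats <- cohort$patients
  for (fl in cohort_flags()) pats[[fl]] <- as.integer(pats[[fl]])
  utils::write.csv(pats, patients_path, row.names = FALSE)

  fr <- cohort$fractures[, c("patient_id", "rib", "side", "percent")]
  # full double precision so the round trip is exact
  fr$percent <- sprintf("%.17g", fr$percent)
  utils::write.csv(fr, fractures_path, row.names = FALSE, quote = 1)
  invisible(c(patients_path, fractures_path))
}
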