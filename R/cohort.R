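#' Cohort container for NB-UVB phototherapy burden studies
#'
#' A `uvb_cohort` bundles three tibbles: `patients` (demographics and
#' phenotype), `courses` (one phototherapy course per patient: minimal
#' erythema dose, exposures, cumulative dose) and `measurements` (paired
#' pre/post mutation burdens per patient and body site). Constructors
#' validate the domain invariants: positive doses, one course per measured
#' patient, at most one measurement per patient and site, sites restricted
#' to `"buttock"` and `"forearm"`.
#'
#' @param patients tibble with columns `patient_id`, `sex` (`"F"`/`"M"`),
#'   `age` (years, > 0), `ethnicity`, `hair_colour`, `eye_colour`,
#'   `darkest_tan`, `freckling`, `prior_phototherapy` (logical),
#'   `prior_phototherapy_type`.
#' @param courses tibble with columns `patient_id`, `med_sed` (standard
#'   erythema doses), `med_jcm2` (J cm^-2), `n_exposures`, `total_dose_sed`.
#' @param measurements tibble with columns `patient_id`, `site`,
#'   `burden_pre`, `burden_post` (substitutions per Mb),
#'   `days_to_second_biopsy`.
#' @return An object of class `uvb_cohort`.
#' @seealso [nbuvb_cohort()], [read_cohort()], [write_cohort()]
#' @export
uvb_cohort <- function(patients, courses, measurements) {
  out <- structure(
    list(
      patients = tibble::as_tibble(patients),
      courses = tibble::as_tibble(courses),
      measurements = tibble::as_tibble(measurements)
    ),
    class = "uvb_cohort"
  )
  validate_cohort(out)
}

cohort_sites <- c("buttock", "forearm")

#' Validate a cohort against its domain invariants
#'
#' Checks field types, positivity constraints, the consistency of the
#' minimal erythema dose expressed in SED against its J cm^-2 equivalent
#' (1 J cm^-2 = 5.7 SED, to 1-decimal rounding), uniqueness of patients,
#' the one-course-per-measured-patient rule and the at-most-one-measurement
#' per (patient, site) rule.
#'
#' @param cohort a `uvb_cohort`.
#' @return `cohort`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "uvb_cohort"))
  p <- cohort$patients; cr <- cohort$courses; m <- cohort$measurements

  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing) > 0) {
      abort(sprintf("cohort %s table lacks column(s): %s", what,
                    paste(missing, collapse = ", ")),
            class = "uvb_schema_error")
    }
  }
  need(p, c("patient_id", "sex", "age"), "patients")
  need(cr, c("patient_id", "med_sed", "med_jcm2", "n_exposures", "total_dose_sed"),
       "courses")
  need(m, c("patient_id", "site", "burden_pre", "burden_post",
            "days_to_second_biopsy"), "measurements")

  fail <- function(msg) abort(msg, class = "uvb_integrity_error")

  if (anyDuplicated(p$patient_id)) fail("duplicate patient_id in patients table")
  if (nrow(p) > 0 && any(p$age <= 0)) fail("patient age must be > 0")
  if (nrow(p) > 0 && !all(p$sex %in% c("F", "M"))) fail("sex must be 'F' or 'M'")

  if (nrow(cr) > 0) {
    if (any(cr$med_sed <= 0)) fail("med_sed must be > 0")
    if (any(cr$total_dose_sed <= 0)) fail("total_dose_sed must be > 0")
    if (any(cr$n_exposures < 1)) fail("n_exposures must be >= 1")
    # MED in SED must agree with MED in J cm^-2 at the 5.7 conversion,
    # within rounding of the printed value to 1 decimal place
    if (any(abs(cr$med_sed - cr$med_jcm2 * 5.7) > 0.05 + 1e-9)) {
      fail("med_sed inconsistent with med_jcm2 at 5.7 SED per J cm^-2")
    }
    if (anyDuplicated(cr$patient_id)) fail("more than one course per patient")
  }

  if (nrow(m) > 0) {
    if (!all(m$site %in% cohort_sites)) {
      fail(sprintf("unknown site value(s): %s; sites must be one of %s",
                   paste(setdiff(unique(m$site), cohort_sites), collapse = ", "),
                   paste(cohort_sites, collapse = ", ")))
    }
    if (any(m$burden_pre < 0) || any(m$burden_post < 0)) {
      fail("burdens must be >= 0")
    }
    if (any(m$days_to_second_biopsy < 0)) fail("days_to_second_biopsy must be >= 0")
    if (anyDuplicated(m[c("patient_id", "site")])) {
      fail("more than one measurement for the same (patient_id, site)")
    }
    orphan <- setdiff(m$patient_id, cr$patient_id)
    if (length(orphan) > 0) {
      fail(sprintf("measurement(s) without a course record: patient %s",
                   paste(orphan, collapse = ", ")))
    }
  }
  invisible(cohort)
}

#' @export
print.uvb_cohort <- function(x, ...) {
  cat(sprintf(
    "<uvb_cohort> %d patients, %d courses, %d measurements (%s)\n",
    nrow(x$patients), nrow(x$courses), nrow(x$measurements),
    paste(sprintf("%s: %d", cohort_sites,
                  vapply(cohort_sites,
                         function(s) sum(x$measurements$site == s), 0L)),
          collapse = ", ")
  ))
  invisible(x)
}

# wide per-measurement schema used for CSV/JSON serialisation
cohort_schema <- c(
  "patient_id", "sex", "age", "ethnicity", "hair_colour", "eye_colour",
  "darkest_tan", "freckling", "prior_phototherapy", "prior_phototherapy_type",
  "med_sed", "med_jcm2", "n_exposures", "total_dose_sed",
  "site", "burden_pre", "burden_post", "days_to_second_biopsy"
)

#' Flatten a cohort to one row per measurement
#'
#' Joins the measurement, course and patient tables into the wide tabular
#' schema used by [write_cohort()] and [read_cohort()].
#'
#' @param x a `uvb_cohort`.
#' @param ... unused.
#' @return A tibble with one row per measurement.
#' @importFrom tibble as_tibble
#' @method as_tibble uvb_cohort
#' @export
as_tibble.uvb_cohort <- function(x, ...) {
  x$measurements %>%
    dplyr::left_join(x$courses, by = "patient_id") %>%
    dplyr::left_join(x$patients, by = "patient_id") %>%
    dplyr::select(dplyr::all_of(cohort_schema))
}

#' The packaged NB-UVB phototherapy cohort
#'
#' Transcription of the study cohort: 15 psoriasis patients treated with a
#' course of NB-UVB, with paired pre/post-course epidermal mutation-burden
#' measurements from infrequently sun-exposed (buttock, n = 14) and
#' frequently sun-exposed (dorsal forearm, n = 10) skin, measured by duplex
#' (NanoSeq) sequencing, alongside each patient's minimal erythema dose,
#' number of exposures and cumulative erythemally weighted course dose.
#' Burdens are substitutions per Mb at 3-decimal precision; doses are in
#' standard erythema doses (SED; 1 J cm^-2 of NB-UVB = 5.7 SED).
#'
#' @return A validated [uvb_cohort()].
#' @examples
#' cohort <- nbuvb_cohort()
#' cohort
#' @export
nbuvb_cohort <- function() {
  patients <- tibble::tribble(
    ~patient_id, ~sex, ~age, ~ethnicity, ~hair_colour, ~eye_colour,
    ~darkest_tan, ~freckling, ~prior_phototherapy, ~prior_phototherapy_type,
    "1",  "M", 26L, "White Irish",   "Light brown",  "Blue/blue",   "Light golden", TRUE,  FALSE, NA_character_,
    "2",  "M", 37L, "Asian other",   "Black",        "Brown/brown", "Dark brown",   FALSE, FALSE, NA_character_,
    "3",  "F", 30L, "White British", "Light brown",  "Grey/green",  "Medium brown", TRUE,  TRUE,  "UVB",
    "4",  "M", 50L, "Asian Indian",  "Black",        "Tan/brown",   "Dark brown",   FALSE, TRUE,  "UVB",
    "6",  "F", 20L, "White British", "Ash brown",    "Yellow/tan",  "Medium brown", FALSE, TRUE,  "NB-UVB",
    "7",  "F", 24L, "White British", "Medium brown", "Blue/grey",   "Light golden", FALSE, FALSE, NA_character_,
    "8",  "M", 73L, "White British", "Ash blonde",   "Grey/tan",    "Medium brown", FALSE, TRUE,  "PUVA, NB-UVB",
    "10", "M", 55L, "White British", "Medium brown", "Grey/green",  "Dark brown",   FALSE, TRUE,  "NB-UVB",
    "11", "F", 26L, "White British", "Light brown",  "Blue/grey",   "Light golden", FALSE, FALSE, NA_character_,
    "12", "M", 32L, "White British", "Dark brown",   "Tan/brown",   "Light golden", TRUE,  TRUE,  "NB-UVB",
    "14", "M", 60L, "White British", "Dark brown",   "Grey/green",  "Dark brown",   FALSE, FALSE, NA_character_,
    "15", "F", 59L, "White British", "Dark brown",   "Grey/blue",   "Medium brown", TRUE,  TRUE,  "NB-UVB",
    "17", "M", 52L, "White British", "Dark brown",   "Brown/brown", "Dark brown",   TRUE,  TRUE,  "NB-UVB",
    "18", "F", 34L, "White British", "Dark brown",   "Grey/tan",    "Medium brown", FALSE, TRUE,  "NB-UVB",
    "19", "M", 26L, "White British", "Ash blonde",   "Green/tan",   "Light golden", TRUE,  TRUE,  "type unknown"
  )

  courses <- tibble::tribble(
    ~patient_id, ~med_sed, ~med_jcm2, ~n_exposures, ~total_dose_sed,
    "1",  2.9, 0.5, 33L, 165,
    "2",  5.1, 0.9, 30L, 756,
    "3",  1.7, 0.3, 23L, 151,
    "4",  4.0, 0.7, 14L,  84,
    "6",  2.9, 0.5, 28L, 183,
    "7",  2.3, 0.4, 35L, 375,
    "8",  1.7, 0.3, 29L, 237,
    "10", 2.9, 0.5, 28L, 427,
    "11", 1.7, 0.3, 34L, 217,
    "12", 2.9, 0.5, 30L, 192,
    "14", 5.1, 0.9, 21L, 128,
    "15", 1.7, 0.3, 26L, 219,
    "17", 1.7, 0.3, 35L, 529,
    "18", 1.7, 0.3, 28L, 224,
    "19", 2.9, 0.5, 28L, 419
  )

  measurements <- tibble::tribble(
    ~patient_id, ~site, ~burden_pre, ~burden_post, ~days_to_second_biopsy,
    "1",  "buttock", 0.072, 0.685,  34L,
    "2",  "buttock", 0.098, 0.260,  11L,
    "3",  "buttock", 0.575, 1.576,  28L,
    "4",  "buttock", 0.195, 0.225,  82L,
    "6",  "buttock", 0.434, 0.799,  13L,
    "7",  "buttock", 0.081, 0.853,  10L,
    "8",  "buttock", 1.174, 1.613,  22L,
    "10", "buttock", 0.830, 1.219,  22L,
    "11", "buttock", 0.207, 0.679,  14L,
    "12", "buttock", 0.801, 1.622,  61L,
    "15", "buttock", 2.740, 3.599, 105L,
    "17", "buttock", 1.478, 2.191, 105L,
    "18", "buttock", 1.065, 1.836,  98L,
    "19", "buttock", 0.470, 0.966,  12L,
    "6",  "forearm", 0.950, 2.217,  13L,
    "7",  "forearm", 1.996, 2.584,  10L,
    "8",  "forearm", 5.199, 6.681,  22L,
    "10", "forearm", 4.069, 5.198,  22L,
    "11", "forearm", 2.547, 2.372,  14L,
    "12", "forearm", 4.967, 5.793,  61L,
    "14", "forearm", 2.337, 2.337,   7L,
    "17", "forearm", 7.498, 10.591, 105L,
    "18", "forearm", 3.578, 4.524,  98L,
    "19", "forearm", 2.688, 3.024,  12L
  )

  uvb_cohort(patients, courses, measurements)
}

#' Read a cohort from its wide CSV serialisation
#'
#' Expects one row per measurement in the schema written by
#' [write_cohort()]. A header-only file yields an empty cohort. Rows that
#' violate the domain invariants (negative burden, unknown site, duplicated
#' patient/site, ...) raise an integrity error; a missing column raises a
#' schema error naming the column.
#'
#' @param path path to a CSV file (UTF-8, header row, dot decimal).
#' @return A validated [uvb_cohort()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file does not exist: %s", path), class = "uvb_io_error")
  }
  wide <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    age = readr::col_integer(),
    ethnicity = readr::col_character(),
    hair_colour = readr::col_character(),
    eye_colour = readr::col_character(),
    darkest_tan = readr::col_character(),
    freckling = readr::col_logical(),
    prior_phototherapy = readr::col_logical(),
    prior_phototherapy_type = readr::col_character(),
    med_sed = readr::col_double(),
    med_jcm2 = readr::col_double(),
    n_exposures = readr::col_integer(),
    total_dose_sed = readr::col_double(),
    site = readr::col_character(),
    burden_pre = readr::col_double(),
    burden_post = readr::col_double(),
    days_to_second_biopsy = readr::col_integer()
  ))
  missing <- setdiff(cohort_schema, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("cohort file lacks column(s): %s", paste(missing, collapse = ", ")),
          class = "uvb_schema_error")
  }
  cohort_from_wide(wide)
}

cohort_from_wide <- function(wide) {
  patients <- wide %>%
    dplyr::distinct(.data$patient_id, .data$sex, .data$age, .data$ethnicity,
                    .data$hair_colour, .data$eye_colour, .data$darkest_tan,
                    .data$freckling, .data$prior_phototherapy,
                    .data$prior_phototherapy_type)
  courses <- wide %>%
    dplyr::distinct(.data$patient_id, .data$med_sed, .data$med_jcm2,
                    .data$n_exposures, .data$total_dose_sed)
  measurements <- wide %>%
    dplyr::select("patient_id", "site", "burden_pre", "burden_post",
                  "days_to_second_biopsy")
  uvb_cohort(patients, courses, measurements)
}

#' Write a cohort to CSV or JSON
#'
#' CSV uses the wide one-row-per-measurement schema of [as_tibble.uvb_cohort()]
#' and round-trips losslessly through [read_cohort()]. JSON mirrors the same
#' schema as an array of records.
#'
#' @param cohort a `uvb_cohort`.
#' @param path destination file.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_cohort(cohort)
  wide <- as_tibble.uvb_cohort(cohort)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("cannot write cohort: directory does not exist: %s",
                  dirname(path)), class = "uvb_io_error")
  }
  if (format == "csv") {
    readr::write_csv(wide, path, na = "")
  } else {
    jsonlite::write_json(wide, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
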