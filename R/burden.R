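#' Per-measurement derived burden quantities
#'
#' For every measurement in the cohort, computes the burden increment
#' `delta = burden_post - burden_pre` (substitutions per Mb), the fold
#' change `burden_post / burden_pre`, and the dose-normalised increment
#' `delta_per_dose = delta / total_dose_sed` (substitutions per Mb per
#' SED) — the quantity modelled downstream as a function of the minimal
#' erythema dose. Course parameters are carried along for convenience.
#'
#' A zero pre-treatment burden makes the fold change undefined; the row is
#' kept with `fold_change = NA` and `fold_defined = FALSE` rather than
#' raising an error, so batch pipelines continue.
#'
#' @param cohort a [uvb_cohort()].
#' @return A tibble with one row per measurement: `patient_id`, `site`,
#'   `med_sed`, `n_exposures`, `total_dose_sed`, `burden_pre`,
#'   `burden_post`, `days_to_second_biopsy`, `delta`, `fold_change`,
#'   `fold_defined`, `delta_per_dose`.
#' @examples
#' nbuvb_cohort() %>% derive_burdens()
#' @export
derive_burdens <- function(cohort) {
  validate_cohort(cohort)
  cohort$measurements %>%
    dplyr::left_join(cohort$courses, by = "patient_id") %>%
    dplyr::mutate(
      delta = .data$burden_post - .data$burden_pre,
      fold_defined = .data$burden_pre > 0,
      fold_change = dplyr::if_else(.data$fold_defined,
                                   .data$burden_post / .data$burden_pre,
                                   NA_real_),
      delta_per_dose = .data$delta / .data$total_dose_sed
    ) %>%
    dplyr::select("patient_id", "site", "med_sed", "n_exposures",
                  "total_dose_sed", "burden_pre", "burden_post",
                  "days_to_second_biopsy", "delta", "fold_change",
                  "fold_defined", "delta_per_dose")
}

#' Median and range of a derived burden quantity
#'
#' Summarises one column of a derived-burden table (or any tibble), overall
#' or per site. The median is the midpoint of the order statistics (mean of
#' the two central values for even n); the range is (min, max).
#'
#' @param data a tibble, typically from [derive_burdens()].
#' @param var unquoted column to summarise (e.g. `burden_pre`, `delta`).
#' @param by optional unquoted grouping column (e.g. `site`).
#' @return A tibble with columns `n`, `median`, `min`, `max` (plus the
#'   grouping column when `by` is given).
#' @examples
#' nbuvb_cohort() %>% derive_burdens() %>% burden_summary(delta, by = site)
#' @export
burden_summary <- function(data, var, by = NULL) {
  var <- rlang::enquo(var)
  by <- rlang::enquo(by)
  if (nrow(data) == 0) {
    abort("cannot summarise an empty selection", class = "uvb_estimation_error")
  }
  grouped <- if (rlang::quo_is_null(by)) data else dplyr::group_by(data, !!by)
  out <- grouped %>%
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(!!var),
      min = min(!!var),
      max = max(!!var),
      .groups = "drop"
    )
  if (any(out$n == 0)) {
    abort("cannot summarise an empty selection", class = "uvb_estimation_error")
  }
  out
}
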