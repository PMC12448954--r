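#' Lifetime NB-UVB exposures to reach a critical mutation burden
#'
#' Projects the number of NB-UVB exposures at which the cumulative mutation
#' burden on habitually covered body sites (trunk and limbs) reaches the
#' average burden of keratinocyte cancer:
#' \deqn{N = M_{exposures} \times (C / S_{MED}) / (M_{dose} + H \times E_{annual})}
#' where `M_exposures` is the median number of exposures per treatment
#' course, `C` the critical burden (default 50 substitutions per Mb, the
#' cutaneous squamous cell carcinoma average; 65 for basal cell carcinoma),
#' `S_MED` the increase in burden per SED of course dose for the patient's
#' MED (see [predict_s()]), `M_dose` the median course dose in SED, `H` the
#' projection horizon in years and `E_annual` the assumed annual solar
#' exposure of trunk and limbs in SED per year. The count is linear in the
#' critical burden and inversely proportional to `S_MED`.
#'
#' @param s_med increase in mutation burden per SED of course dose
#'   (substitutions per Mb per SED), > 0. Vectorised.
#' @param annual_exposure_sed assumed annual solar exposure to trunk and
#'   limbs (SED per year): 10 for sun-cautious, 30 for typical, 90 for
#'   sun-enthusiastic behaviour.
#' @param m_exposures median exposures per course (default 28, the
#'   packaged-cohort median).
#' @param m_dose_sed median course dose in SED (default 219, the
#'   packaged-cohort median).
#' @param critical_burden substitutions per Mb at which surveillance is
#'   indicated (default 50).
#' @param horizon_years years of accumulated annual exposure (default 80).
#' @return Unrounded exposure count(s); round at presentation time.
#' @examples
#' lifetime_exposures(0.0026, annual_exposure_sed = 10)
#' @export
lifetime_exposures <- function(s_med, annual_exposure_sed,
                               m_exposures = 28, m_dose_sed = 219,
                               critical_burden = 50, horizon_years = 80) {
  if (any(s_med <= 0)) {
    abort("s_med must be > 0", class = "uvb_domain_error")
  }
  stopifnot(annual_exposure_sed > 0, m_exposures > 0, m_dose_sed > 0,
            critical_burden > 0, horizon_years > 0)
  m_exposures * (critical_burden / s_med) /
    (m_dose_sed + horizon_years * annual_exposure_sed)
}

default_med_grid_jcm2 <- c(0.2, 0.3, 0.35, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
default_behaviours <- c(cautious = 10, typical = 30, enthusiastic = 90)

#' Surveillance-threshold table over MED and sun-behaviour grids
#'
#' For each MED (given in J cm^-2 and converted to SED) and each
#' sun-behaviour category, computes the projected lifetime NB-UVB exposure
#' count of [lifetime_exposures()] using the dose-response prediction
#' [predict_s()] at that MED. When a [bootstrap_ci()] object is supplied,
#' interval bounds for each cell are propagated from the `S(MED)` bootstrap
#' intervals (a larger `S` means a smaller exposure count, so the bounds
#' swap). Counts within a row decrease as annual exposure grows; within a
#' behaviour column they increase with MED whenever `b > 0`.
#'
#' @param fit a [fit_dose_response()] result.
#' @param med_grid_jcm2 MED grid in J cm^-2 (default the conventional
#'   0.2-1.0 clinical grid).
#' @param behaviours named numeric vector of annual trunk-and-limb
#'   exposures in SED per year (default cautious/typical/enthusiastic =
#'   10/30/90).
#' @param horizon_years projection horizon (default 80).
#' @param boot optional `uvb_bootstrap` for interval bounds.
#' @param sed_factor SED per J cm^-2 for the MED conversion (default 5.7).
#' @inheritParams lifetime_exposures
#' @return A tibble of class `uvb_surveillance`, one row per MED x
#'   behaviour: `med_jcm2`, `med_sed`, `behaviour`,
#'   `annual_exposure_sed`, `s_med`, `exposures` (unrounded),
#'   `exposures_rounded` (half-up integer), optional `lower`/`upper`, and
#'   a `horizon_years` column.
#' @examples
#' fit <- nbuvb_cohort() %>% derive_burdens() %>% prepare_points() %>%
#'   fit_dose_response()
#' surveillance_table(fit)
#' @export
surveillance_table <- function(fit, med_grid_jcm2 = default_med_grid_jcm2,
                               behaviours = default_behaviours,
                               horizon_years = 80,
                               m_exposures = 28, m_dose_sed = 219,
                               critical_burden = 50, boot = NULL,
                               sed_factor = 5.7) {
  stopifnot(inherits(fit, "uvb_dose_fit") || (is.list(fit) &&
              all(c("A", "b") %in% names(fit))))
  if (is.null(names(behaviours))) {
    names(behaviours) <- paste0("annual_", behaviours, "_sed")
  }
  grid <- tidyr::expand_grid(
    med_jcm2 = med_grid_jcm2,
    behaviour = factor(names(behaviours), levels = names(behaviours))
  ) %>%
    dplyr::mutate(
      med_sed = jcm2_to_sed(.data$med_jcm2, sed_factor),
      annual_exposure_sed = unname(behaviours[as.character(.data$behaviour)]),
      s_med = predict_s(fit, .data$med_sed),
      exposures = lifetime_exposures(
        .data$s_med, .data$annual_exposure_sed,
        m_exposures = m_exposures, m_dose_sed = m_dose_sed,
        critical_burden = critical_burden, horizon_years = horizon_years
      ),
      # round half-up for presentation; full precision retained alongside
      exposures_rounded = floor(.data$exposures + 0.5),
      horizon_years = horizon_years
    )

  if (!is.null(boot)) {
    stopifnot(inherits(boot, "uvb_bootstrap"))
    tmethod <- "t"
    s_lo <- s_hi <- numeric(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      m <- grid$med_sed[i]
      s_draws <- boot$draws[, "A"] * exp(-boot$draws[, "b"] * m^2)
      est <- grid$s_med[i]
      tq <- stats::qt(1 - (1 - boot$level) / 2,
                      df = length(unique(fit$points$patient_id)) - 1)
      if (tmethod == "t") {
        s_lo[i] <- max(est - tq * stats::sd(s_draws), .Machine$double.xmin)
        s_hi[i] <- est + tq * stats::sd(s_draws)
      }
    }
    grid <- grid %>%
      dplyr::mutate(
        lower = lifetime_exposures(s_hi, .data$annual_exposure_sed,
                                   m_exposures, m_dose_sed,
                                   critical_burden, horizon_years),
        upper = lifetime_exposures(s_lo, .data$annual_exposure_sed,
                                   m_exposures, m_dose_sed,
                                   critical_burden, horizon_years)
      )
  }
  class(grid) <- c("uvb_surveillance", class(grid))
  grid
}

#' Surveillance tables across projection horizons
#'
#' Recomputes [surveillance_table()] for several horizons (by default 80,
#' 60 and 40 years of the same annual sun exposure) and binds them into a
#' single long table. Shorter horizons accumulate less solar dose, so every
#' cell strictly increases as the horizon shrinks.
#'
#' @inheritParams surveillance_table
#' @param horizons numeric vector of horizons in years.
#' @return A `uvb_surveillance` tibble with a `horizon_years` column.
#' @export
horizon_variants <- function(fit, horizons = c(80, 60, 40), ...) {
  out <- purrr::map_dfr(horizons, function(h) {
    surveillance_table(fit, horizon_years = h, ...)
  })
  class(out) <- c("uvb_surveillance", class(tibble::tibble()))
  out
}

#' @export
print.uvb_surveillance <- function(x, ...) {
  # after column subsetting the wide layout may no longer apply
  needed <- c("horizon_years", "med_jcm2", "med_sed", "behaviour",
              "exposures_rounded")
  if (!all(needed %in% names(x))) {
    return(NextMethod())
  }
  for (h in unique(x$horizon_years)) {
    cat(sprintf("Projected NB-UVB exposures to critical burden (%d-year horizon)\n",
                h))
    wide <- x %>%
      dplyr::filter(.data$horizon_years == h) %>%
      dplyr::mutate(cell = .data$exposures_rounded) %>%
      dplyr::select("med_jcm2", "med_sed", "behaviour", "cell") %>%
      tidyr::pivot_wider(names_from = "behaviour", values_from = "cell")
    print(as.data.frame(wide), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Surveillance thresholds against MED
#'
#' Log-scale exposure counts against MED, one line per sun-behaviour
#' category, facetted by horizon when several are present.
#'
#' @param object a `uvb_surveillance` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot uvb_surveillance
#' @export
autoplot.uvb_surveillance <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$med_sed, y = .data$exposures,
                                    colour = .data$behaviour)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "MED (SED)", y = "Projected NB-UVB exposures",
                  colour = "Sun behaviour") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$horizon_years) > 1) {
    p <- p + ggplot2::facet_wrap(~horizon_years,
                                 labeller = ggplot2::label_both)
  }
  p
}
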