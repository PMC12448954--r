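#' Regression points for the dose-response fit
#'
#' Turns a derived-burden table into the point set for the exponential
#' dose-response model. The model is fitted on the natural logarithm of
#' the dose-normalised burden increment, so measurements with a
#' non-positive increment cannot enter the fit: negative increments are
#' excluded as biologically implausible treatment effects, zero increments
#' because their logarithm is undefined. Exclusions are marked, with a
#' reason, never silently dropped.
#'
#' @param derived tibble from [derive_burdens()] (needs `patient_id`,
#'   `site`, `med_sed`, `delta_per_dose`).
#' @return A tibble with columns `patient_id`, `site`, `med_sed`,
#'   `delta_per_dose`, `included` (logical), `exclusion_reason`.
#' @examples
#' nbuvb_cohort() %>% derive_burdens() %>% prepare_points()
#' @export
prepare_points <- function(derived) {
  if (nrow(derived) == 0) {
    abort("derived burden table is empty", class = "uvb_domain_error")
  }
  derived %>%
    dplyr::mutate(
      included = .data$delta_per_dose > 0,
      exclusion_reason = dplyr::case_when(
        .data$delta_per_dose < 0 ~ "negative delta per dose",
        .data$delta_per_dose == 0 ~ "zero delta per dose (log undefined)",
        TRUE ~ NA_character_
      )
    ) %>%
    dplyr::select("patient_id", "site", "med_sed", "delta_per_dose",
                  "included", "exclusion_reason")
}

# closed-form simple OLS; the hot path used by the bootstrap and the
# recovery experiment (numerically identical to lm on the same data)
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

.fit_ab <- function(med_sed, delta_per_dose) {
  co <- .ols(med_sed^2, log(delta_per_dose))
  c(A = unname(exp(co["intercept"])), b = unname(-co["slope"]))
}

#' Fit the exponential dose-response model
#'
#' Fits `S(MED) = A * exp(-b * MED^2)` — the dose-normalised burden
#' increment as a function of the patient's minimal erythema dose in SED —
#' by ordinary least squares of `ln(delta_per_dose)` on `MED^2` over the
#' included points. `b` is minus the slope, `A` the exponentiated
#' intercept; `se_b` is the standard OLS slope standard error.
#'
#' @param points tibble from [prepare_points()].
#' @return An object of class `uvb_dose_fit`: a list with elements `A`,
#'   `b`, `se_b`, `se_log_A`, `n_points`, `residual_sd` (log scale),
#'   `excluded` (tibble of excluded points with reasons), `model` (the
#'   underlying `lm`), `points`.
#' @examples
#' fit <- nbuvb_cohort() %>% derive_burdens() %>% prepare_points() %>%
#'   fit_dose_response()
#' fit
#' tidy(fit)
#' @export
fit_dose_response <- function(points) {
  used <- dplyr::filter(points, .data$included)
  if (nrow(used) < 3) {
    abort("need at least 3 included points", class = "uvb_fit_error")
  }
  if (dplyr::n_distinct(used$med_sed) < 2) {
    abort("need at least 2 distinct MED values", class = "uvb_fit_error")
  }
  df <- data.frame(med2 = used$med_sed^2, log_s = log(used$delta_per_dose))
  model <- stats::lm(log_s ~ med2, data = df)
  # summary.lm warns on an exactly interpolating fit (legitimate in the
  # noise-free limit); the zero residual SD is the correct answer there
  sm <- suppressWarnings(summary(model))
  structure(
    list(
      A = unname(exp(coef(model)[1])),
      b = unname(-coef(model)[2]),
      se_b = sm$coefficients["med2", "Std. Error"],
      se_log_A = sm$coefficients["(Intercept)", "Std. Error"],
      n_points = nrow(used),
      residual_sd = sm$sigma,
      r_squared = sm$r.squared,
      excluded = dplyr::filter(points, !.data$included),
      model = model,
      points = points
    ),
    class = "uvb_dose_fit"
  )
}

#' @export
print.uvb_dose_fit <- function(x, ...) {
  cat("<uvb_dose_fit>  S(MED) = A * exp(-b * MED^2)\n")
  cat(sprintf("  A = %.4g (log-scale SE %.3g)\n", x$A, x$se_log_A))
  cat(sprintf("  b = %.3g +/- %.2g per SED^2\n", x$b, x$se_b))
  cat(sprintf("  %d points fitted, %d excluded; residual SD (log) %.3g\n",
              x$n_points, nrow(x$excluded), x$residual_sd))
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x a `uvb_dose_fit`.
#' @param ... unused.
#' @method tidy uvb_dose_fit
#' @export
tidy.uvb_dose_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "b"),
    estimate = c(x$A, x$b),
    # SE of A by the delta method from the log-scale intercept SE
    std.error = c(x$A * x$se_log_A, x$se_b)
  )
}

#' @rdname fit_dose_response
#' @method glance uvb_dose_fit
#' @export
glance.uvb_dose_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    nobs = x$n_points,
    n_excluded = nrow(x$excluded)
  )
}

#' Predicted dose-response at a given MED
#'
#' Evaluates `S(MED) = A * exp(-b * MED^2)` — the expected increase in
#' mutation burden per SED of course dose for a patient with minimal
#' erythema dose `med_sed`. Strictly decreasing in MED when `b > 0`; tends
#' to `A` as MED tends to 0.
#'
#' @param fit a `uvb_dose_fit`, or any list with elements `A` and `b`.
#' @param med_sed MED value(s) in SED, > 0.
#' @return Substitutions per Mb per SED.
#' @export
predict_s <- function(fit, med_sed) {
  if (any(med_sed <= 0)) {
    abort("med_sed must be > 0", class = "uvb_domain_error")
  }
  fit$A * exp(-fit$b * med_sed^2)
}

#' Cluster bootstrap intervals for the dose-response fit
#'
#' Resamples patients with replacement (a patient's buttock and forearm
#' points move together — the cluster bootstrap) and refits the model in
#' each resample. Degenerate resamples (< 3 usable points or a single MED
#' value) are redrawn and counted. Two interval constructions are
#' reported for `A`, `b` and, optionally, for `S(MED)` on a grid:
#'
#' * `t`: the symmetric interval `estimate +/- t_{G-1} * sd(boot)`, where
#'   G is the number of patient clusters — the package's primary interval,
#'   chosen because with few clusters the percentile interval undercovers;
#' * `percentile`: the classical percentile interval, reported alongside.
#'
#' @param points tibble from [prepare_points()].
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level (default 0.95).
#' @param med_grid optional MED values (SED) at which to interval `S(MED)`.
#' @return An object of class `uvb_bootstrap`: list with `ci` (tibble:
#'   `term`, `estimate`, `lower`, `upper`, `method`), `s_med_ci` (tibble or
#'   NULL), `draws` (n_boot x 2 matrix of A, b), `n_redraws`, `n_boot`,
#'   `seed`, `level`.
#' @export
bootstrap_ci <- function(points, n_boot = 2000, seed = 1, level = 0.95,
                         med_grid = NULL) {
  if (n_boot < 200) {
    abort("n_boot must be >= 200", class = "uvb_domain_error")
  }
  fit0 <- fit_dose_response(points)
  pid <- points$patient_id
  med <- points$med_sed
  dpd <- points$delta_per_dose
  inc <- points$included
  idx <- split(seq_along(pid), pid)
  G <- length(idx)

  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("A", "b")))
  n_redraws <- 0L
  for (j in seq_len(n_boot)) {
    repeat {
      rows <- unlist(idx[sample.int(G, G, replace = TRUE)], use.names = FALSE)
      keep <- rows[inc[rows]]
      if (length(keep) >= 3 && length(unique(med[keep])) >= 2) {
        draws[j, ] <- .fit_ab(med[keep], dpd[keep])
        break
      }
      n_redraws <- n_redraws + 1L
    }
  }

  alpha <- (1 - level) / 2
  tq <- stats::qt(1 - alpha, df = G - 1)
  ci_for <- function(term, est, d) {
    q <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
    tibble::tibble(
      term = term,
      estimate = est,
      lower = c(est - tq * stats::sd(d), q[1]),
      upper = c(est + tq * stats::sd(d), q[2]),
      method = c("t", "percentile")
    )
  }
  ci <- dplyr::bind_rows(
    ci_for("A", fit0$A, draws[, "A"]),
    ci_for("b", fit0$b, draws[, "b"])
  )

  s_med_ci <- NULL
  if (!is.null(med_grid)) {
    s_med_ci <- purrr::map_dfr(med_grid, function(m) {
      s_draws <- draws[, "A"] * exp(-draws[, "b"] * m^2)
      est <- predict_s(fit0, m)
      q <- stats::quantile(s_draws, c(alpha, 1 - alpha), names = FALSE)
      tibble::tibble(
        med_sed = m,
        estimate = est,
        lower = c(max(est - tq * stats::sd(s_draws), .Machine$double.xmin), q[1]),
        upper = c(est + tq * stats::sd(s_draws), q[2]),
        method = c("t", "percentile")
      )
    })
  }

  structure(
    list(ci = ci, s_med_ci = s_med_ci, draws = draws, n_redraws = n_redraws,
         n_boot = n_boot, seed = seed, level = level, fit = fit0),
    class = "uvb_bootstrap"
  )
}

#' @export
print.uvb_bootstrap <- function(x, ...) {
  cat(sprintf("<uvb_bootstrap> %d cluster resamples (seed %d, %.0f%% level, %d redraws)\n",
              x$n_boot, x$seed, 100 * x$level, x$n_redraws))
  print(x$ci)
  invisible(x)
}

#' Dose-response scatter and fitted curve
#'
#' Plots the per-measurement dose-normalised burden increments against
#' MED, the fitted exponential decay curve, and marks excluded points.
#'
#' @param object a `uvb_dose_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot uvb_dose_fit
#' @export
autoplot.uvb_dose_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(med_sed = seq(min(pts$med_sed) * 0.8,
                                       max(pts$med_sed) * 1.05,
                                       length.out = 200))
  grid$s <- predict_s(object, grid$med_sed)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$med_sed, y = .data$delta_per_dose)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$s),
                       linewidth = 0.7, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$site,
                                     colour = .data$included), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "red"),
                                 labels = c(`TRUE` = "fitted", `FALSE` = "excluded"),
                                 name = NULL) +
    ggplot2::labs(
      x = "MED (SED)",
      y = expression(Delta * "-burden / dose (substitutions " * Mb^-1 * " " * SED^-1 * ")"),
      title = sprintf("S(MED) = %.4f exp(-%.2f MED²)", object$A, object$b)
    ) +
    ggplot2::theme_minimal()
}
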