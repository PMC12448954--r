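# one-row tidy result shared by all cohort-level tests
test_result <- function(method, statistic, p_value, n, estimate = NA_real_,
                        exact = NA, note = NA_character_) {
  tibble::tibble(
    method = method,
    statistic = as.numeric(statistic),
    p.value = as.numeric(p_value),
    estimate = as.numeric(estimate),
    n = n,
    exact = exact,
    note = note
  )
}

#' Paired Wilcoxon signed-rank test on pre/post burdens
#'
#' Two-tailed Wilcoxon signed-rank test of paired measurements. Zero
#' differences are dropped before ranking (Wilcoxon's original treatment);
#' the exact null distribution is used for n <= 25 effective pairs when the
#' absolute differences are free of ties, otherwise the normal
#' approximation with continuity correction. When every difference is zero
#' the statistic is undefined and the result is flagged (`note`), not an
#' error.
#'
#' @param pre,post equal-length numeric vectors paired by patient.
#' @return One-row tibble: `method`, `statistic` (V, the positive-rank
#'   sum), `p.value`, `n` (pairs after dropping zeros), `exact`, `note`.
#' @examples
#' d <- nbuvb_cohort() %>% derive_burdens() %>% dplyr::filter(site == "buttock")
#' paired_test(d$burden_pre, d$burden_post)
#' @export
paired_test <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(test_result("wilcoxon_signed_rank", NA, NA, 0L,
                       note = "undefined: all differences zero"))
  }
  use_exact <- n <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = use_exact,
                                            correct = TRUE))
  test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value, n,
              exact = use_exact)
}

#' Two-sample distribution comparison
#'
#' Two-sided Kolmogorov-Smirnov or Mann-Whitney (rank-sum) comparison of
#' two independent samples. With `exact = "auto"` the exact null
#' distribution is used whenever feasible at the given sample sizes (no
#' ties; for Mann-Whitney, m + n below the stats-package exact threshold),
#' otherwise the asymptotic distribution with continuity correction; the
#' branch actually taken is recorded in the `exact` column.
#'
#' @param a,b numeric samples (both non-empty).
#' @param method `"kolmogorov_smirnov"` or `"mann_whitney"`.
#' @param exact `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @return One-row tibble as in [paired_test()]; `statistic` is D for KS,
#'   W (the Mann-Whitney U of the first sample) for the rank-sum test;
#'   `n` is `c(length(a), length(b))` packed as a list-column-free pair in
#'   `n` = m + n with `note` recording both sizes.
#' @export
two_sample_test <- function(a, b,
                            method = c("kolmogorov_smirnov", "mann_whitney"),
                            exact = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  exact <- match.arg(exact)
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty", class = "uvb_domain_error")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  want_exact <- switch(exact,
    auto = !ties,
    exact = TRUE,
    asymptotic = FALSE
  )
  if (method == "kolmogorov_smirnov") {
    ht <- suppressWarnings(stats::ks.test(a, b, exact = want_exact))
    ran_exact <- want_exact && !ties
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = want_exact,
                                              correct = TRUE))
    ran_exact <- want_exact && !ties
  }
  test_result(method, ht$statistic, ht$p.value, length(a) + length(b),
              exact = ran_exact,
              note = sprintf("n1=%d, n2=%d", length(a), length(b)))
}

#' Correlation between two burden quantities
#'
#' Pearson or Spearman correlation with a two-sided p-value. Spearman uses
#' mid-ranks for ties (asymptotic p in that case). Zero variance in either
#' vector makes the coefficient undefined; the result is flagged, not an
#' error.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble; `estimate` is r (or rho), `statistic` the test
#'   statistic (t for Pearson, S for Spearman).
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) {
    abort("need at least 3 paired observations", class = "uvb_domain_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(test_result(paste0(method, "_correlation"), NA, NA, length(x),
                       note = "undefined: zero variance"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  test_result(paste0(method, "_correlation"), ct$statistic, ct$p.value,
              length(x), estimate = ct$estimate)
}

#' Spearman rank trend
#'
#' Convenience wrapper around [correlation_test()] with
#' `method = "spearman"`: monotone-association test with mid-rank tie
#' handling, used for dose-response screening (e.g. dose-normalised burden
#' increment against MED, or against time since last exposure).
#'
#' @inheritParams correlation_test
#' @return One-row tibble; `estimate` is rho.
#' @export
rank_trend <- function(x, y) {
  correlation_test(x, y, method = "spearman")
}

#' Compare linear, power-law and exponential models of burden vs age
#'
#' Least-squares fits of `y = a + c x` (linear), `y = c x^k` (power law)
#' and `y = c exp(k x)` (exponential), ranked by the coefficient of
#' determination computed on the original scale for all three. The
#' nonlinear forms are initialised from the corresponding log-scale linear
#' fit and refined by Gauss-Newton least squares; when refinement is
#' degenerate (e.g. an exact zero-residual fit), the log-scale-initialised
#' parameters are used directly. Non-positive burdens make the power and
#' exponential forms unfit; those rows carry `r_squared = NA`.
#'
#' @param age,burden equal-length numeric vectors, n >= 4.
#' @return A tibble with one row per model: `model`, `r_squared`, `rank`
#'   (1 = best), and the fitted parameters `par1` (a or c) and `par2`
#'   (c or k).
#' @examples
#' d <- nbuvb_cohort() %>% derive_burdens() %>% dplyr::filter(site == "buttock")
#' ages <- nbuvb_cohort()$patients$age[match(d$patient_id,
#'                                           nbuvb_cohort()$patients$patient_id)]
#' age_model_comparison(ages, d$burden_pre)
#' @export
age_model_comparison <- function(age, burden) {
  stopifnot(length(age) == length(burden))
  if (length(age) < 4) {
    abort("need at least 4 observations", class = "uvb_domain_error")
  }
  ss_tot <- sum((burden - mean(burden))^2)
  r2 <- function(fitted) 1 - sum((burden - fitted)^2) / ss_tot

  lin <- stats::lm(burden ~ age)
  rows <- list(tibble::tibble(model = "linear", r_squared = r2(fitted(lin)),
                              par1 = unname(coef(lin)[1]),
                              par2 = unname(coef(lin)[2])))

  fit_nl <- function(model_name, formula, start) {
    refined <- tryCatch(
      suppressWarnings(
        stats::nls(formula, data = data.frame(age = age, burden = burden),
                   start = start,
                   control = stats::nls.control(warnOnly = TRUE))
      ),
      error = function(e) NULL
    )
    pars <- if (is.null(refined)) unlist(start) else coef(refined)
    fitted_vals <- if (model_name == "power") {
      pars[["c0"]] * age^pars[["k"]]
    } else {
      pars[["c0"]] * exp(pars[["k"]] * age)
    }
    tibble::tibble(model = model_name, r_squared = r2(fitted_vals),
                   par1 = unname(pars[["c0"]]), par2 = unname(pars[["k"]]))
  }

  if (all(burden > 0)) {
    logfit_p <- stats::lm(log(burden) ~ log(age))
    rows <- c(rows, list(fit_nl("power", burden ~ c0 * age^k,
      list(c0 = exp(unname(coef(logfit_p)[1])), k = unname(coef(logfit_p)[2])))))
    logfit_e <- stats::lm(log(burden) ~ age)
    rows <- c(rows, list(fit_nl("exponential", burden ~ c0 * exp(k * age),
      list(c0 = exp(unname(coef(logfit_e)[1])), k = unname(coef(logfit_e)[2])))))
  } else {
    rows <- c(rows, list(
      tibble::tibble(model = "power", r_squared = NA_real_,
                     par1 = NA_real_, par2 = NA_real_),
      tibble::tibble(model = "exponential", r_squared = NA_real_,
                     par1 = NA_real_, par2 = NA_real_)
    ))
  }
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(dplyr::desc(.data$r_squared)) %>%
    dplyr::mutate(rank = dplyr::if_else(is.na(.data$r_squared), NA_integer_,
                                        dplyr::row_number()))
}

#' Compare mutation changes attributed to UVR vs ageing signatures
#'
#' Mann-Whitney comparison of the per-patient post-course change in
#' mutation counts attributed to ultraviolet-radiation signatures
#' (SBS7a/b/d) against the change attributed to ageing signatures
#' (SBS1, SBS5). Attributed counts are inputs — from an external signature
#' assignment or from [generate_cohort()]'s ground truth — never computed
#' from sequence data here.
#'
#' @param uv_changes,ageing_changes per-patient attributed count changes.
#' @return One-row tibble as in [two_sample_test()].
#' @export
attributed_change_test <- function(uv_changes, ageing_changes) {
  two_sample_test(uv_changes, ageing_changes, method = "mann_whitney")
}
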