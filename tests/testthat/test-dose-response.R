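fixture_points <- nbuvb_cohort() %>% derive_burdens() %>% prepare_points()

test_that("point preparation marks the two non-positive measurements", {
  expect_equal(nrow(fixture_points), 24)
  expect_equal(sum(fixture_points$included), 22)

  p11f <- dplyr::filter(fixture_points, patient_id == "11", site == "forearm")
  expect_false(p11f$included)
  expect_match(p11f$exclusion_reason, "negative")

  p14f <- dplyr::filter(fixture_points, patient_id == "14", site == "forearm")
  expect_false(p14f$included)
  expect_match(p14f$exclusion_reason, "zero")

  allpos <- tibble::tibble(patient_id = letters[1:4], site = "buttock",
                           med_sed = c(1.7, 2.3, 2.9, 4), delta_per_dose = 0.003)
  expect_true(all(prepare_points(allpos)$included))
})

test_that("log-linear fit recovers the cohort decay coefficient", {
  fit <- fit_dose_response(fixture_points)
  expect_equal(round(fit$b, 2), 0.12)
  expect_true(fit$b >= 0.09 && fit$b <= 0.15)
  expect_equal(fit$n_points, 22)
  expect_equal(nrow(fit$excluded), 2)

  # buttock-only variant rounds to the same slope
  btk_fit <- fit_dose_response(dplyr::filter(fixture_points, site == "buttock"))
  expect_equal(round(btk_fit$b, 2), 0.12)
  # slope uncertainty is in line with the reported +/- 0.03
  expect_equal(fit$se_b, 0.03, tolerance = 0.2)
})

test_that("two-point instance is solved in closed form", {
  pts <- tibble::tibble(patient_id = c("a", "b"), site = "buttock",
                        med_sed = c(1, 2),
                        delta_per_dose = c(0.01, 0.01 * exp(-3)))
  fit <- fit_dose_response(prepare_points(rbind(pts, pts)))  # duplicated to pass n >= 3
  expect_equal(fit$b, 1, tolerance = 1e-12)
  expect_equal(fit$A, 0.01 * exp(1), tolerance = 1e-12)
})

test_that("noise-free generated points are interpolated exactly", {
  A <- 0.005; b <- 0.1
  meds <- c(1.7, 2.9, 5.1)
  pts <- tibble::tibble(patient_id = c("a", "b", "c"), site = "buttock",
                        med_sed = meds,
                        delta_per_dose = A * exp(-b * meds^2))
  fit <- fit_dose_response(prepare_points(pts))
  expect_equal(fit$b, b, tolerance = 1e-11)
  expect_equal(fit$A, A, tolerance = 1e-11)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
})

test_that("OLS agrees with the normal-equation oracle to 12 digits", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    med <- runif(n, 1, 6)
    dpd <- exp(rnorm(n, log(0.003), 0.6))
    pts <- tibble::tibble(patient_id = as.character(seq_len(n)),
                          site = "buttock", med_sed = med,
                          delta_per_dose = dpd)
    fit <- fit_dose_response(prepare_points(pts))
    oracle <- ols_oracle(med^2, log(dpd))
    expect_equal(fit$b, -oracle["slope"], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(log(fit$A), oracle["intercept"], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate point sets raise fit errors", {
  two <- tibble::tibble(patient_id = c("a", "b"), site = "buttock",
                        med_sed = c(1, 2), delta_per_dose = c(0.01, 0.002),
                        included = TRUE, exclusion_reason = NA_character_)
  expect_error(fit_dose_response(two), class = "uvb_fit_error")
  mono <- tibble::tibble(patient_id = c("a", "b", "c"), site = "buttock",
                         med_sed = 2, delta_per_dose = c(0.01, 0.002, 0.05),
                         included = TRUE, exclusion_reason = NA_character_)
  expect_error(fit_dose_response(mono), class = "uvb_fit_error")
})

test_that("predictions follow the exponential decay law", {
  fit <- list(A = 0.0042, b = 0.12)
  expect_equal(predict_s(fit, 2.9), 0.0042 * exp(-0.12 * 2.9^2))
  expect_equal(predict_s(fit, 2.9), 0.00153, tolerance = 2e-3)
  # the zero-MED limit is the amplitude; b = 0 gives a flat response
  expect_equal(predict_s(fit, 1e-9), 0.0042, tolerance = 1e-6)
  expect_equal(predict_s(list(A = 0.0042, b = 0), c(1, 3, 5)),
               rep(0.0042, 3))
  grid <- seq(0.5, 6, by = 0.25)
  s <- predict_s(fit, grid)
  expect_true(all(diff(s) < 0))
  # log-prediction is linear in MED^2
  expect_equal(diff(log(s)) / diff(grid^2), rep(-0.12, length(grid) - 1))
  expect_error(predict_s(fit, 0), class = "uvb_domain_error")
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_dose_response(fixture_points)
  td <- tidy(fit)
  expect_equal(td$term, c("A", "b"))
  expect_equal(td$estimate[2], fit$b)
  gl <- glance(fit)
  expect_equal(gl$nobs, 22)
  expect_equal(gl$n_excluded, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("cluster bootstrap is seed-deterministic and brackets the slope", {
  b1 <- bootstrap_ci(fixture_points, n_boot = 2000, seed = 42)
  b2 <- bootstrap_ci(fixture_points, n_boot = 2000, seed = 42)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_ci(fixture_points, n_boot = 2000, seed = 43)
  expect_false(identical(b3$ci$lower, b1$ci$lower))

  for (m in c("t", "percentile")) {
    ci_b <- dplyr::filter(b1$ci, term == "b", method == m)
    expect_lt(ci_b$lower, 0.12)
    expect_gt(ci_b$upper, 0.12)
  }
  expect_error(bootstrap_ci(fixture_points, n_boot = 50),
               class = "uvb_domain_error")
})

test_that("bootstrap S(MED) intervals are positive and ordered", {
  bs <- bootstrap_ci(fixture_points, n_boot = 400, seed = 5,
                     med_grid = c(1.7, 2.9, 5.1))
  sm <- bs$s_med_ci
  expect_true(all(sm$lower > 0))
  expect_true(all(sm$lower <= sm$estimate & sm$estimate <= sm$upper))
})
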