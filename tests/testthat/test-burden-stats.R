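fixture_derived <- derive_burdens(nbuvb_cohort())
btk <- dplyr::filter(fixture_derived, site == "buttock")
frm <- dplyr::filter(fixture_derived, site == "forearm")

test_that("derived quantities reproduce representative table rows", {
  p3 <- dplyr::filter(btk, patient_id == "3")
  expect_equal(p3$delta, 1.001)
  expect_equal(p3$fold_change, 2.74, tolerance = 0.05 / 2.74)
  expect_equal(p3$delta_per_dose, 0.0066, tolerance = 0.0002 / 0.0066)

  p14 <- dplyr::filter(frm, patient_id == "14")
  expect_equal(p14$delta, 0)
  expect_equal(p14$fold_change, 1)
  expect_equal(p14$delta_per_dose, 0)
})

test_that("recomputed folds and delta/dose stay within print tolerance", {
  printed <- list(
    buttock = list(fold = c(9.55, 2.65, 2.74, 1.16, 1.84, 10.50, 1.37,
                            1.47, 3.28, 2.02, 1.31, 1.48, 1.72, 2.05),
                   dpd = c(0.0037, 0.0002, 0.0066, 0.0004, 0.0020, 0.0021,
                           0.0019, 0.0009, 0.0022, 0.0043, 0.0039, 0.0013,
                           0.0034, 0.0012)),
    forearm = list(fold = c(2.33, 1.29, 1.29, 1.28, 0.93, 1.17, 1.00,
                            1.41, 1.26, 1.12),
                   dpd = c(0.0069, 0.0016, 0.0063, 0.0026, -0.0008, 0.0043,
                           0.0000, 0.0058, 0.0042, 0.0008))
  )
  for (s in names(printed)) {
    d <- dplyr::filter(fixture_derived, site == s)
    expect_true(all(abs(d$fold_change - printed[[s]]$fold) <= 0.05))
    expect_true(all(abs(d$delta_per_dose - printed[[s]]$dpd) <= 0.0002))
  }
})

test_that("fold change is flagged undefined at zero baseline", {
  co <- toy_cohort()
  co$measurements$burden_pre[1] <- 0
  co$measurements$burden_post[1] <- 0
  d <- derive_burdens(co)
  expect_false(d$fold_defined[1])
  expect_true(is.na(d$fold_change[1]))
  expect_equal(d$delta[1], 0)
})

test_that("burden_summary equals a sort-based oracle on fixture subsets", {
  for (s in c("buttock", "forearm")) {
    d <- dplyr::filter(fixture_derived, site == s)
    for (v in c("burden_pre", "burden_post", "delta", "delta_per_dose")) {
      sm <- burden_summary(d, .data[[v]])
      expect_equal(sm$median, median_oracle(d[[v]]))
      expect_equal(sm$min, min(d[[v]]))
      expect_equal(sm$max, max(d[[v]]))
    }
  }
  one <- burden_summary(fixture_derived[3, ], delta)
  expect_equal(one$median, fixture_derived$delta[3])
  expect_equal(one$min, one$max)
  expect_error(burden_summary(fixture_derived[0, ], delta),
               class = "uvb_estimation_error")
})

test_that("paired signed-rank test reproduces the cohort p-values exactly", {
  wb <- paired_test(btk$burden_pre, btk$burden_post)
  # all 14 differences positive: the extreme tail of the exact null
  expect_true(wb$exact)
  expect_equal(wb$p.value, 2 / 2^14)
  expect_lt(wb$p.value, 0.001)

  wf <- paired_test(frm$burden_pre, frm$burden_post)
  # one zero difference dropped (n = 9), one negative of smallest rank
  expect_equal(wf$n, 9)
  expect_equal(wf$p.value, 0.0078125)
  expect_equal(round(wf$p.value, 2), 0.01)

  same <- paired_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(same$p.value))
  expect_match(same$note, "all differences zero")
})

test_that("exact signed-rank p matches brute-force enumeration for n <= 12", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(4:11, 1)
    pre <- runif(n, 0, 2)
    post <- pre + rnorm(n, 0.2, 0.5)
    got <- paired_test(pre, post)
    expect_equal(got$p.value, signed_rank_p_bruteforce(post - pre),
                 tolerance = 1e-12)
  }
})

test_that("two-sample comparisons reproduce the cohort statistics", {
  # site difference in baseline burden: exact branch is even more extreme
  # than the printed asymptotic 0.001
  ks_exact <- two_sample_test(btk$burden_pre, frm$burden_pre)
  expect_true(ks_exact$exact)
  expect_lt(ks_exact$p.value, 0.001)
  ks_asym <- two_sample_test(btk$burden_pre, frm$burden_pre,
                             exact = "asymptotic")
  expect_equal(round(ks_asym$p.value, 3), 0.001)

  mw <- two_sample_test(btk$delta_per_dose, frm$delta_per_dose,
                        method = "mann_whitney")
  expect_equal(round(mw$p.value, 2), 0.55)

  self <- two_sample_test(btk$burden_pre, btk$burden_pre)
  expect_equal(self$statistic, 0, ignore_attr = TRUE)
  expect_equal(self$p.value, 1)
})

test_that("correlations reproduce the matched-site analysis", {
  matched <- dplyr::inner_join(
    dplyr::select(btk, patient_id, b = burden_pre),
    dplyr::select(frm, patient_id, f = burden_pre),
    by = "patient_id"
  )
  expect_equal(nrow(matched), 9)
  ct <- correlation_test(matched$b, matched$f)
  expect_equal(round(ct$estimate, 3), 0.867)
  expect_lt(ct$p.value, 0.005)

  perfect <- correlation_test(1:5, (1:5) * 2)
  expect_equal(perfect$estimate, 1)

  flat <- correlation_test(1:5, rep(2, 5))
  expect_true(is.na(flat$estimate))
  expect_match(flat$note, "zero variance")
})

test_that("rank trends recover the direction of the dose-response screen", {
  med_trend <- rank_trend(btk$delta_per_dose, btk$med_sed)
  expect_lt(med_trend$estimate, 0)
  expect_lt(med_trend$p.value, 0.05)

  days_trend <- rank_trend(btk$delta_per_dose, btk$days_to_second_biopsy)
  expect_equal(round(days_trend$p.value, 2), 0.23)

  mono <- rank_trend(1:6, c(2, 3, 5, 8, 9, 20))
  expect_equal(mono$estimate, 1)
})

test_that("age association with baseline burden is positive at both sites", {
  co <- nbuvb_cohort()
  age_of <- function(d) co$patients$age[match(d$patient_id, co$patients$patient_id)]
  ab <- rank_trend(age_of(btk), btk$burden_pre)
  expect_gt(ab$estimate, 0)
  expect_equal(round(ab$p.value, 2), 0.01)
  af <- rank_trend(age_of(frm), frm$burden_pre)
  expect_gt(af$estimate, 0)
  expect_lt(af$p.value, 0.05)
})

test_that("age model comparison ranks the generating law first", {
  co <- nbuvb_cohort()
  ages <- co$patients$age[match(btk$patient_id, co$patients$patient_id)]
  cmp <- age_model_comparison(ages, btk$burden_pre)
  expect_equal(cmp$model[cmp$rank == 1], "linear")
  expect_equal(nrow(cmp), 3)

  x <- seq(20, 70, by = 5)
  lin <- age_model_comparison(x, 2 * x)
  expect_equal(lin$model[lin$rank == 1], "linear")
  expect_equal(lin$r_squared[lin$model == "linear"], 1)

  ex <- age_model_comparison(x, exp(0.1 * x))
  expect_equal(ex$model[ex$rank == 1], "exponential")
  expect_equal(ex$r_squared[ex$model == "exponential"], 1, tolerance = 1e-9)

  pw <- age_model_comparison(x, 0.01 * x^1.7)
  expect_equal(pw$model[pw$rank == 1], "power")

  withzero <- age_model_comparison(x, c(0, 2 * x[-1]))
  expect_true(all(is.na(withzero$r_squared[withzero$model != "linear"])))
})

test_that("attributed-change comparison detects UV-dominant induction", {
  sim <- generate_cohort(synthetic_config(uv_fraction_of_delta = 0.9),
                         seed = 101)
  tr <- sim$truth
  res <- attributed_change_test(tr$uv_change, tr$ageing_change)
  expect_lt(res$p.value, 0.05)
})

test_that("attributed-change test holds its type-I error at the null", {
  set.seed(77)
  reject <- logical(1000)
  for (i in seq_along(reject)) {
    uv <- rnorm(14, 50, 10)
    ageing <- rnorm(14, 50, 10)
    reject[i] <- attributed_change_test(uv, ageing)$p.value < 0.05
  }
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})
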