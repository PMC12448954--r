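test_that("packaged cohort has the documented shape and key rows", {
  co <- nbuvb_cohort()
  expect_s3_class(co, "uvb_cohort")
  expect_equal(nrow(co$patients), 15)
  expect_equal(dplyr::n_distinct(co$patients$patient_id), 15)
  expect_equal(sum(co$measurements$site == "buttock"), 14)
  expect_equal(sum(co$measurements$site == "forearm"), 10)

  p1 <- dplyr::filter(as_tibble(co), patient_id == "1", site == "buttock")
  expect_equal(p1$med_sed, 2.9)
  expect_equal(p1$n_exposures, 33L)
  expect_equal(p1$total_dose_sed, 165)
  expect_equal(p1$burden_pre, 0.072)
  expect_equal(p1$burden_post, 0.685)
  expect_equal(p1$days_to_second_biopsy, 34L)

  p15 <- dplyr::filter(as_tibble(co), patient_id == "15", site == "buttock")
  expect_equal(p15$burden_pre, 2.740)
  expect_equal(p15$burden_post, 3.599)
  expect_equal(p15$total_dose_sed, 219)

  # patient 14 contributes forearm only
  p14 <- dplyr::filter(co$measurements, patient_id == "14")
  expect_equal(p14$site, "forearm")
  expect_equal(dplyr::filter(co$courses, patient_id == "14")$n_exposures, 21L)
})

test_that("course medians over the 15 patients match the cohort summary", {
  co <- nbuvb_cohort()
  expect_equal(median(co$courses$n_exposures), 28)
  expect_equal(median(co$courses$total_dose_sed), 219)
  expect_equal(median(co$courses$med_sed), 2.9)
})

test_that("CSV round-trip is lossless, for the fixture and the builtin", {
  co <- nbuvb_cohort()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, tmp)
  back <- read_cohort(tmp)
  expect_equal(as.data.frame(as_tibble(back)), as.data.frame(as_tibble(co)))

  shipped <- read_cohort(system.file("extdata", "nbuvb_cohort.csv",
                                     package = "uvburden"))
  expect_equal(as.data.frame(as_tibble(shipped)),
               as.data.frame(as_tibble(co)))
})

test_that("header-only file loads as an empty cohort; empty round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  co <- nbuvb_cohort()
  empty <- uvb_cohort(co$patients[0, ], co$courses[0, ], co$measurements[0, ])
  write_cohort(empty, tmp)
  back <- read_cohort(tmp)
  expect_equal(nrow(back$measurements), 0)
  expect_equal(nrow(back$patients), 0)
})

test_that("invariant violations are rejected with informative errors", {
  co <- nbuvb_cohort()

  bad <- co$measurements
  bad$burden_pre[1] <- -0.1
  expect_error(uvb_cohort(co$patients, co$courses, bad),
               class = "uvb_integrity_error")

  bad <- co$measurements
  bad$site[1] <- "scalp"
  expect_error(uvb_cohort(co$patients, co$courses, bad),
               regexp = "unknown site", class = "uvb_integrity_error")

  bad <- dplyr::bind_rows(co$measurements, co$measurements[1, ])
  expect_error(uvb_cohort(co$patients, co$courses, bad),
               regexp = "more than one measurement",
               class = "uvb_integrity_error")

  # measurement without a course
  expect_error(uvb_cohort(co$patients, co$courses[-1, ], co$measurements),
               regexp = "without a course", class = "uvb_integrity_error")

  # MED inconsistency between SED and J cm^-2 beyond 1-dp rounding
  bad <- co$courses
  bad$med_sed[1] <- 9.9
  expect_error(uvb_cohort(co$patients, bad, co$measurements),
               regexp = "inconsistent", class = "uvb_integrity_error")
})

test_that("schema errors name the missing column", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(nbuvb_cohort(), tmp)
  txt <- readLines(tmp)
  txt[1] <- sub("burden_pre", "burden_before", txt[1])
  writeLines(txt, tmp)
  expect_error(suppressWarnings(read_cohort(tmp)), regexp = "burden_pre",
               class = "uvb_schema_error")
  expect_error(read_cohort(file.path(tempdir(), "no-such-file.csv")),
               class = "uvb_io_error")
})

test_that("a file with a negative burden fails integrity on load", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  wide <- as_tibble(nbuvb_cohort())
  wide$burden_pre[3] <- -wide$burden_pre[3]
  readr::write_csv(wide, tmp, na = "")
  expect_error(read_cohort(tmp), class = "uvb_integrity_error")
})

test_that("JSON export mirrors the wide schema", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_cohort(nbuvb_cohort(), tmp, format = "json")
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(nrow(back), 24)
  expect_true(all(c("patient_id", "med_sed", "burden_pre") %in% names(back)))
})
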