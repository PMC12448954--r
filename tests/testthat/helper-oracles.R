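# Independent oracles used across the suite.

# simple OLS by explicit normal equations (solve(), not lm or .ols)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# exact two-tailed signed-rank p-value by enumeration of all 2^n sign
# assignments of the absolute differences (feasible for n <= 12)
signed_rank_p_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# median via explicit sorting and order statistics
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# a minimal three-patient cohort used where the full fixture is overkill
toy_cohort <- function() {
  uvb_cohort(
    patients = tibble::tibble(
      patient_id = c("a", "b", "c"), sex = c("F", "M", "F"),
      age = c(30L, 40L, 50L), ethnicity = NA_character_,
      hair_colour = NA_character_, eye_colour = NA_character_,
      darkest_tan = NA_character_, freckling = NA,
      prior_phototherapy = FALSE, prior_phototherapy_type = NA_character_
    ),
    courses = tibble::tibble(
      patient_id = c("a", "b", "c"), med_sed = c(1.7, 2.9, 5.1),
      med_jcm2 = c(0.3, 0.5, 0.9), n_exposures = c(20L, 25L, 30L),
      total_dose_sed = c(150, 200, 250)
    ),
    measurements = tibble::tibble(
      patient_id = c("a", "b", "c"), site = "buttock",
      burden_pre = c(0.5, 1.0, 1.5), burden_post = c(1.0, 1.6, 1.8),
      days_to_second_biopsy = c(10L, 20L, 30L)
    )
  )
}
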