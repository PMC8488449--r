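# Shared fixtures: cohorts are generated in code and memoised per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default-parameter cohort, cached by (n, seed).
default_cohort <- function(n = 5000, seed = 101) {
  key <- sprintf("default_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      cohort_params(n_children = n, seed = seed))
  }
  .fixture_env[[key]]
}

# Cohort with no ethnicity-education association and no confounder effects
# anywhere: education, intake and confounders mutually independent.
independence_params <- function(n, seed) {
  cohort_params(
    n_children = n, seed = seed,
    confounder_coefs = list(
      education_on_nonwhite = c(low = 0, high = 0),
      birthweight_low_per_level = 0, health_fairbad_per_level = 0,
      activity_low_per_level = 0, tv_high_per_level = 0,
      imd_per_level = 0))
}

# Tiny hand-made cohort rows for toy oracles.
toy_cohort <- function(intake, sex = "male", education = "mid") {
  n <- length(intake)
  tibble::tibble(
    id = seq_len(n),
    sex = factor(rep_len(sex, n), levels = c("male", "female")),
    ethnicity = factor("white", levels = c("white", "non_white")),
    education = factor(rep_len(education, n),
                       levels = c("low", "mid", "high")),
    birthweight_cat = factor("mid", levels = c("low", "mid", "high")),
    health = factor("good", levels = c("good", "fair_bad")),
    activity_cat = factor("mid", levels = c("low", "mid", "high")),
    tv_cat = factor("mid", levels = c("low", "mid", "high")),
    imd_score = 0, imd_quintile = 3L,
    intake_kcal = intake,
    bmi_z_3y = 0, obese_3y = FALSE, bmi_z_6y = 0, obese_6y = FALSE)
}
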