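test_that("parameter validation rejects malformed inputs", {
  expect_error(cohort_params(n_children = 0), class = "kcalmsm_param_error")
  expect_error(cohort_params(male_fraction = 1.4),
               class = "kcalmsm_param_error")
  expect_error(cohort_params(education_probs = c(0.5, 0.4, 0.2)),
               class = "kcalmsm_param_error")
  expect_error(
    cohort_params(intake_model = list(
      median_kcal = c(male = 1311.5, female = 1273.5),
      log_sd = c(male = -1, female = 0.2), education_effect = 0,
      confounder_effects = c(bw_high = 0, health_fairbad = 0,
                             activity_low = 0, tv_high = 0, nonwhite = 0))),
    class = "kcalmsm_param_error")
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_cohort(cohort_params(n_children = 500, seed = 33))
  b <- generate_cohort(cohort_params(n_children = 500, seed = 33))
  expect_identical(a, b)
  c <- generate_cohort(cohort_params(n_children = 500, seed = 34))
  expect_false(identical(a$intake_kcal, c$intake_kcal))
})

test_that("cohort marginals match their calibration targets", {
  cohort <- default_cohort(20000, 101)
  expect_lt(abs(mean(cohort$sex == "male") - 0.513), 0.01)
  edu <- prop.table(table(cohort$education))
  expect_lt(max(abs(edu[c("low", "mid", "high")] -
                      c(0.094, 0.664, 0.242))), 0.01)
  expect_lt(abs(mean(cohort$ethnicity == "white") - 0.961), 0.005)
  expect_lt(abs(median(cohort$intake_kcal[cohort$sex == "male"]) - 1311.5),
            15)
  expect_lt(abs(median(cohort$intake_kcal[cohort$sex == "female"]) - 1273.5),
            15)
})

test_that("zero education effect leaves intake and education uncorrelated", {
  cohort <- default_cohort(20000, 101)
  r <- cor(ifelse(cohort$education == "low", 2,
                  ifelse(cohort$education == "mid", 1, 0)),
           log(cohort$intake_kcal))
  expect_lt(abs(r), 0.025) # ~3 / sqrt(n)
})

test_that("with all confounder coefficients zero, variables decouple", {
  cohort <- generate_cohort(independence_params(20000, 77))
  code <- ifelse(cohort$education == "low", 2,
                 ifelse(cohort$education == "mid", 1, 0))
  expect_lt(abs(cor(code, as.integer(cohort$ethnicity == "non_white"))),
            0.025)
  expect_lt(abs(cor(code, as.integer(cohort$tv_cat == "high"))), 0.025)
  expect_lt(abs(cor(log(cohort$intake_kcal),
                    as.integer(cohort$activity_cat == "low"))), 0.025)
})

test_that("obesity flags are consistent with z-scores and the 95th-centile cut", {
  cohort <- default_cohort(5000, 101)
  expect_identical(cohort$obese_6y, cohort$bmi_z_6y > qnorm(0.95))
  expect_identical(cohort$obese_3y, cohort$bmi_z_3y > qnorm(0.95))
  expect_true(all(cohort$intake_kcal > 0))
  expect_false(anyDuplicated(cohort$id) > 0)
})

test_that("ground truth travels with the cohort", {
  cohort <- default_cohort(500, 101)
  truth <- attr(cohort, "truth")
  expect_s3_class(truth, "cohort_params")
  expect_equal(truth$outcome_model$intake_coef, 0.10)
})

test_that("missingness: zero probabilities change nothing", {
  cohort <- default_cohort(500, 101)
  out <- impose_missingness(cohort,
                            missingness_spec(c(intake_kcal = 0), seed = 5))
  expect_equal(out, cohort, ignore_attr = TRUE)
})

test_that("MCAR masking hits its target rate", {
  cohort <- default_cohort(10000, 101)
  out <- impose_missingness(cohort,
                            missingness_spec(c(intake_kcal = 0.5), seed = 5))
  frac <- mean(is.na(out$intake_kcal))
  expect_lt(abs(frac - 0.5), 2.576 * sqrt(0.25 / 10000)) # binomial 99%
})

test_that("MAR-on-education orders masking by disadvantage", {
  cohort <- default_cohort(20000, 101)
  out <- impose_missingness(
    cohort, missingness_spec(c(intake_kcal = 0.2),
                             mechanism = "MAR_education",
                             education_or = 2, seed = 5))
  frac <- tapply(is.na(out$intake_kcal), out$education, mean)
  expect_true(frac[["low"]] > frac[["mid"]])
  expect_true(frac[["mid"]] > frac[["high"]])
})

test_that("exposure and outcome can never be masked", {
  cohort <- default_cohort(500, 101)
  expect_error(impose_missingness(cohort,
                                  missingness_spec(c(education = 0.1))),
               class = "kcalmsm_param_error")
  expect_error(impose_missingness(cohort,
                                  missingness_spec(c(obese_6y = 0.1))),
               class = "kcalmsm_param_error")
})

test_that("cohort files round-trip, including missing markers and truth", {
  cohort <- impose_missingness(
    default_cohort(400, 101),
    missingness_spec(c(intake_kcal = 0.3, tv_cat = 0.2), seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort),
               ignore_attr = TRUE)
  expect_equal(attr(back, "truth")$outcome_model$intake_coef,
               attr(cohort, "truth")$outcome_model$intake_coef)
})

test_that("malformed cohort files are rejected with a pointed error", {
  cohort <- default_cohort(50, 101)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)

  txt <- readLines(path)
  bad <- sub(",mid,", ",phd,", txt[2], fixed = TRUE)
  writeLines(c(txt[1], bad, txt[-(1:2)]), path)
  expect_error(read_cohort(path), class = "kcalmsm_parse_error")

  write_cohort(cohort, path)
  txt <- readLines(path)
  fields <- strsplit(txt[2], ",")[[1]]
  fields[which(names(cohort) == "intake_kcal")] <- "-100"
  writeLines(c(txt[1], paste(fields, collapse = ","), txt[-(1:2)]), path)
  expect_error(read_cohort(path), class = "kcalmsm_parse_error")
})
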