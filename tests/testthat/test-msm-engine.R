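test_that("weighted logistic fit honours weight semantics", {
  cohort <- default_cohort(2000, 101)
  f0 <- fit_weighted_logistic(cohort, obese_6y ~ education)
  f1 <- fit_weighted_logistic(cohort, obese_6y ~ education,
                              weights = rep(3, nrow(cohort)))
  expect_equal(f0$coefficients, f1$coefficients, tolerance = 1e-6)

  # duplicated rows with unit weights == single rows with weight 2
  dup <- dplyr::bind_rows(cohort, cohort)
  fd <- fit_weighted_logistic(dup, obese_6y ~ education + I(intake_kcal / 100))
  fw <- fit_weighted_logistic(cohort, obese_6y ~ education + I(intake_kcal / 100),
                              weights = rep(2, nrow(cohort)))
  expect_equal(fd$coefficients, fw$coefficients, tolerance = 1e-6)

  expect_error(fit_weighted_logistic(cohort, obese_6y ~ education,
                                     weights = rep(-1, nrow(cohort))),
               class = "kcalmsm_fit_error")
  expect_error(fit_weighted_logistic(cohort, bmi_z_6y ~ education),
               class = "kcalmsm_fit_error")
})

test_that("tidy and glance expose the fit in broom shape", {
  cohort <- default_cohort(2000, 101)
  fit <- fit_weighted_logistic(cohort, obese_6y ~ education)
  td <- tidy(fit, conf.int = TRUE)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_effective, nrow(cohort))
  expect_true(gl$converged)
})

test_that("CDE recovers the generating coefficients within 3 robust SEs", {
  cohort <- default_cohort(20000, 101)
  truth <- attr(cohort, "truth")$outcome_model
  cde <- estimate_cde(cohort, ci_method = "delta")
  td <- tidy(cde$fit_cat)
  # factor reference is "low": mid term = b_mid - b_low, high term = -b_low
  true_vals <- c(
    educationmid = truth$education_coef[["mid"]] -
      truth$education_coef[["low"]],
    educationhigh = -truth$education_coef[["low"]],
    `I(intake_kcal/100)` = truth$intake_coef)
  for (term in names(true_vals)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - true_vals[[term]]), 3 * row$std.error)
  }
})

test_that("predict-then-average equals brute-force per-child averaging", {
  cohort <- default_cohort(5000, 101)
  cde <- estimate_cde(cohort, ci_method = "delta")
  overall <- cde$prevalence$estimate[cde$prevalence$group == "overall"]
  beta <- cde$fit_cat$coefficients
  X <- model.matrix(~ education + I(intake_kcal / 100), data = cohort)
  brute <- mean(plogis(as.numeric(X %*% beta[colnames(X)])))
  expect_equal(overall, brute, tolerance = 1e-10)
})

test_that("unadjusted model is saturated in the three education groups", {
  cohort <- default_cohort(4000, 101)
  est <- estimate_unadjusted(cohort, ci_method = "delta")
  emp <- tapply(cohort$obese_6y, cohort$education, mean)
  prev <- est$prevalence
  for (g in c("low", "mid", "high")) {
    expect_equal(prev$estimate[prev$group == g], unname(emp[[g]]),
                 tolerance = 1e-6)
  }
  expect_equal(prev$estimate[prev$group == "overall"], mean(cohort$obese_6y),
               tolerance = 1e-6)
})

test_that("identical group rates give RR 1 and RD 0", {
  set.seed(8)
  n <- 3000
  cohort <- toy_cohort(rlnorm(n, log(1300), 0.2),
                       education = sample(c("low", "mid", "high"), n, TRUE))
  cohort$obese_6y <- rep(c(TRUE, rep(FALSE, 9)), length.out = n)[sample(n)]
  # force exactly equal rates per group by construction
  cohort$obese_6y <- FALSE
  for (g in c("low", "mid", "high")) {
    idx <- which(cohort$education == g)
    cohort$obese_6y[idx[seq_len(round(0.1 * length(idx)))]] <- TRUE
  }
  est <- estimate_unadjusted(cohort, ci_method = "delta")
  expect_equal(est$inequality$rr, 1, tolerance = 0.02)
  expect_equal(est$inequality$rd, 0, tolerance = 0.2)
})

test_that("inequality arithmetic: fitted 10% vs 5% gives RR 2 and RD 5pp", {
  cohort <- toy_cohort(rep(1300, 200),
                       education = rep(c("low", "high"), each = 100))
  cohort$obese_6y <- c(rep(TRUE, 10), rep(FALSE, 90),
                       rep(TRUE, 5), rep(FALSE, 95))
  fit <- fit_weighted_logistic(
    dplyr::mutate(cohort, edu_code = ifelse(education == "low", 2, 0)),
    obese_6y ~ edu_code)
  m <- inequality_metrics(fit, cohort)
  expect_equal(m$rr, 2.0, tolerance = 1e-6)
  expect_equal(m$rd, 5.0, tolerance = 1e-6)
  expect_true(m$rr_lo <= m$rr & m$rr <= m$rr_hi)
  expect_true(m$rd_lo <= m$rd & m$rd <= m$rd_hi)
})

test_that("delta CI widths shrink like 1/sqrt(n)", {
  widths <- vapply(c(1000, 4000, 16000), function(n) {
    est <- estimate_unadjusted(default_cohort(n, 303), ci_method = "delta")
    est$inequality$rd_hi - est$inequality$rd_lo
  }, numeric(1))
  expect_gt(widths[1] / widths[2], 1.4)
  expect_lt(widths[1] / widths[2], 2.9)
  expect_gt(widths[2] / widths[3], 1.4)
  expect_lt(widths[2] / widths[3], 2.9)
})

test_that("bootstrap CIs contain the point estimate", {
  cohort <- default_cohort(2000, 101)
  est <- estimate_cde(cohort, ci_method = "bootstrap", boot_reps = 59,
                      seed = 17)
  expect_true(est$inequality$rr_lo <= est$inequality$rr)
  expect_true(est$inequality$rr <= est$inequality$rr_hi)
  expect_true(est$inequality$rd_lo <= est$inequality$rd)
  expect_true(est$inequality$rd <= est$inequality$rd_hi)
})

test_that("an irrelevant mediator leaves CDE at the unadjusted answer", {
  p <- independence_params(20000, 31)
  p$outcome_model$intake_coef <- 0
  p$outcome_model$intercept <- -3.1
  cohort <- generate_cohort(p)
  unadj <- estimate_unadjusted(cohort, ci_method = "delta")
  cde <- estimate_cde(cohort, ci_method = "delta")
  expect_equal(cde$prevalence$estimate, unadj$prevalence$estimate,
               tolerance = 0.01)
})

test_that("chained imputation restores masked data faithfully", {
  cohort <- default_cohort(10000, 404)
  masked <- impose_missingness(cohort,
                               missingness_spec(c(intake_kcal = 0.2),
                                                seed = 6))
  imp <- chained_imputation(masked, m = 3, seed = 11, cycles = 3)
  expect_length(imp$imputations, 3)
  meds <- vapply(imp$imputations,
                 function(d) median(d$intake_kcal), numeric(1))
  expect_lt(abs(mean(meds) - median(cohort$intake_kcal)) /
              median(cohort$intake_kcal), 0.02)
  expect_false(anyNA(imp$imputations[[1]]$intake_kcal))
  # distinct sub-seeds give distinct imputations
  expect_false(identical(imp$imputations[[1]]$intake_kcal,
                         imp$imputations[[2]]$intake_kcal))
})

test_that("imputation handles categorical columns and m = 50", {
  cohort <- default_cohort(400, 505)
  masked <- impose_missingness(
    cohort, missingness_spec(c(intake_kcal = 0.2, tv_cat = 0.2,
                               health = 0.15), seed = 2))
  imp <- chained_imputation(masked, m = 50, seed = 3, cycles = 2)
  expect_length(imp$imputations, 50)
  expect_false(anyNA(imp$imputations[[50]][c("intake_kcal", "tv_cat",
                                             "health")]))
})

test_that("a complete cohort passes through imputation unchanged", {
  cohort <- default_cohort(400, 505)
  imp <- chained_imputation(cohort, m = 4, seed = 3)
  for (d in imp$imputations) expect_identical(d, cohort)
})

test_that("Rubin pooling reproduces hand-computed values", {
  pooled <- rubin_pool(c(1, 3), c(1, 1))
  expect_equal(pooled$estimate, 2)
  expect_equal(pooled$between_var, 2)
  expect_equal(pooled$total_var, 1 + 1.5 * 2)

  same <- rubin_pool(c(2, 2, 2), c(0.5, 0.5, 0.5))
  expect_equal(same$estimate, 2)
  expect_equal(same$between_var, 0)
  expect_equal(same$total_var, 0.5)

  expect_warning(one <- rubin_pool(5, 2))
  expect_equal(one$estimate, 5)
  expect_equal(one$total_var, 2)
  expect_error(rubin_pool(numeric(0), numeric(0)),
               class = "kcalmsm_param_error")
})
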