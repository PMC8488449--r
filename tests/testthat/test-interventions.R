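test_that("universal reduction reproduces the printed kcal arithmetic", {
  r <- compute_universal_reduction(c(male = 1311.5, female = 1273.5),
                                   c(male = 1171.0, female = 1076.0),
                                   male_fraction = 0.513)
  expect_equal(r$absolute_reduction[r$sex == "male"], 140.5)
  expect_equal(r$absolute_reduction[r$sex == "female"], 197.5)
  expect_equal(round(100 * r$percent_reduction[r$sex == "male"], 1), 10.7)
  expect_equal(round(100 * r$percent_reduction[r$sex == "female"], 1), 15.5)
  expect_equal(round(100 * attr(r, "overall_percent"), 1), 13.0)

  r0 <- compute_universal_reduction(c(male = 1171, female = 1076),
                                    c(male = 1171, female = 1076), 0.5)
  expect_equal(r0$absolute_reduction, c(0, 0))
  expect_equal(attr(r0, "overall_percent"), 0)
  expect_error(compute_universal_reduction(c(male = -1, female = 1),
                                           c(male = 1, female = 1), 0.5),
               class = "kcalmsm_param_error")
})

test_that("eligibility rules and uptake behave as declared", {
  cohort <- default_cohort(20000, 101)
  all1 <- select_eligible(cohort, scenario_spec("x", "all", uptake = 1))
  expect_true(all(all1$treated))

  s75 <- select_eligible(cohort, scenario_spec("x", "all", uptake = 0.75,
                                               seed = 3))
  frac <- mean(s75$treated)
  expect_lt(abs(frac - 0.75), 2.576 * sqrt(0.75 * 0.25 / 20000))

  # 6-row toy straddling the sex-specific EARs
  toy <- toy_cohort(c(1000, 1171, 1172, 1050, 1076, 1100),
                    sex = c("male", "male", "male",
                            "female", "female", "female"))
  m <- select_eligible(toy, scenario_spec("x", "above_ear",
                                          "truncate_to_ear", uptake = 1))
  expect_equal(m$eligible, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))

  spec_imd <- scenario_spec("x", "imd_high", "percent", percent = 0.2)
  el <- select_eligible(cohort, spec_imd)$eligible
  cut <- mean(cohort$imd_score) + sd(cohort$imd_score)
  expect_identical(el, cohort$imd_score >= cut)

  expect_error(select_eligible(dplyr::select(cohort, -imd_score), spec_imd),
               class = "kcalmsm_schema_error")
})

test_that("capping at the EAR yields full compliance", {
  cohort <- default_cohort(10000, 101)
  app <- apply_scenario(cohort, scenario_spec("cap", "above_ear",
                                              "truncate_to_ear", uptake = 1))
  prop <- proportion_at_or_below_ear(app$cohort)
  expect_equal(prop$proportion, c(1, 1))
  ear <- ifelse(app$cohort$sex == "male", 1171, 1076)
  expect_true(all(app$cohort$intake_kcal <= ear))
})

test_that("zero uptake leaves the cohort untouched", {
  cohort <- default_cohort(2000, 101)
  app <- apply_scenario(cohort, scenario_spec("null", "all", "percent",
                                              percent = 0.3, uptake = 0))
  expect_identical(app$cohort$intake_kcal, cohort$intake_kcal)
})

test_that("percent reductions match a row-by-row oracle with flooring", {
  toy <- toy_cohort(c(800, 1200, 1500, 2000, 900))
  spec <- scenario_spec("pct", "all", "percent", percent = 0.213,
                        uptake = 1, seed = 2)
  app <- apply_scenario(toy, spec)
  bound <- mean(toy$intake_kcal) - 2 * sd(toy$intake_kcal)
  oracle <- pmax(toy$intake_kcal * (1 - 0.213), bound)
  oracle[toy$intake_kcal < bound] <- toy$intake_kcal[toy$intake_kcal < bound]
  expect_equal(app$cohort$intake_kcal, oracle, tolerance = 1e-12)
  expect_equal(app$lower_bound, bound)

  # heavier cut so the floor binds for some children
  toy2 <- toy_cohort(c(1000, 1010, 1020, 1030, 1500))
  spec2 <- scenario_spec("half", "all", "percent", percent = 0.5, uptake = 1)
  app2 <- apply_scenario(toy2, spec2)
  bound2 <- mean(toy2$intake_kcal) - 2 * sd(toy2$intake_kcal)
  expect_true(any(app2$cohort$intake_kcal == bound2))
  expect_true(all(app2$cohort$intake_kcal >= bound2))
})

test_that("intakes never increase and the floor protects low consumers", {
  cohort <- default_cohort(5000, 101)
  specs <- build_builtin_scenarios(cohort, seed = 5)
  for (sp in specs) {
    app <- apply_scenario(cohort, sp)
    expect_true(all(app$cohort$intake_kcal <= cohort$intake_kcal + 1e-9))
    below <- cohort$intake_kcal < app$lower_bound
    expect_identical(app$cohort$intake_kcal[below],
                     cohort$intake_kcal[below])
    expect_true(all(app$cohort$intake_kcal[!below] >=
                      app$lower_bound - 1e-9))
    expect_true(all(app$cohort$intake_kcal[!app$treated] ==
                      cohort$intake_kcal[!app$treated]))
  }
})

test_that("shift-rule jitter is mean-preserving within sex", {
  cohort <- default_cohort(20000, 101)
  spec <- scenario_spec("s1", "all", "shift_median_to_ear", uptake = 1,
                        variability_sd = c(male = 35, female = 49),
                        lower_bound = FALSE, seed = 6)
  app <- apply_scenario(cohort, spec)
  red <- app$reduction
  for (s in c("male", "female")) {
    idx <- app$treated & cohort$sex == s
    target <- red$absolute_reduction[red$sex == s]
    shift <- cohort$intake_kcal[idx] - app$cohort$intake_kcal[idx]
    # exact up to the never-increase clamp, which almost never binds here
    expect_lt(abs(mean(shift) - target), 0.5)
    expect_gt(sd(shift), 20) # jitter actually present
  }
})

test_that("proportion at or below the EAR uses an inclusive threshold", {
  toy <- toy_cohort(c(1000, 1171, 1172, 1500))
  prop <- proportion_at_or_below_ear(toy)
  expect_equal(prop$proportion[prop$sex == "male"], 0.5)
  expect_true(is.na(prop$proportion[prop$sex == "female"]))

  allover <- toy_cohort(c(2000, 2100), sex = c("male", "female"))
  expect_equal(proportion_at_or_below_ear(allover)$proportion, c(0, 0))
})

test_that("g-computation of scenario impact matches a brute-force loop", {
  cohort <- default_cohort(4000, 101)
  cde <- estimate_cde(cohort, ci_method = "delta")
  spec <- scenario_spec("pct", "all", "percent", percent = 0.15,
                        uptake = 0.8, seed = 4)
  sim <- simulate_impact(cohort, spec, cde)
  beta <- cde$fit_cat$coefficients
  X <- model.matrix(~ education + I(intake_kcal / 100), data = sim$cohort)
  brute <- mean(plogis(as.numeric(X %*% beta[colnames(X)])))
  expect_equal(sim$prevalence$estimate[sim$prevalence$group == "overall"],
               brute, tolerance = 1e-10)
})

test_that("scenario impact is monotone in the reduction magnitude", {
  cohort <- default_cohort(5000, 101)
  cde <- estimate_cde(cohort, ci_method = "delta")
  expect_gt(cde$fit_cat$coefficients[["I(intake_kcal/100)"]], 0)
  prev <- vapply(c(0.05, 0.15, 0.30), function(p) {
    sim <- simulate_impact(cohort,
                           scenario_spec("pct", "all", "percent", percent = p,
                                         uptake = 1, seed = 4), cde)
    sim$prevalence$estimate[sim$prevalence$group == "overall"]
  }, numeric(1))
  expect_true(all(diff(prev) < 0))
})

test_that("a null scenario and a zeroed intake coefficient change nothing", {
  cohort <- default_cohort(3000, 101)
  cde <- estimate_cde(cohort, ci_method = "delta")
  null_sim <- simulate_impact(cohort,
                              scenario_spec("null", "all", "percent",
                                            percent = 0.3, uptake = 0), cde)
  expect_equal(null_sim$prevalence$estimate, cde$prevalence$estimate,
               tolerance = 1e-12)
  expect_equal(null_sim$prevalence$pct_change_vs_cde, rep(0, 4),
               tolerance = 1e-9)

  doctored <- cde
  doctored$fit_cat$coefficients[["I(intake_kcal/100)"]] <- 0
  doctored$fit_cat$glm$coefficients[["I(intake_kcal/100)"]] <- 0
  doctored$fit_cont$coefficients[["I(intake_kcal/100)"]] <- 0
  doctored$fit_cont$glm$coefficients[["I(intake_kcal/100)"]] <- 0
  doctored$prevalence <- kcalmsm:::build_prevalence_report(doctored$fit_cat,
                                                           cohort, "cde")
  sim <- simulate_impact(cohort,
                         scenario_spec("pct", "all", "percent",
                                       percent = 0.3, uptake = 1, seed = 2),
                         doctored)
  expect_equal(sim$prevalence$estimate, doctored$prevalence$estimate,
               tolerance = 1e-12)
})

test_that("built-in scenarios encode the declared policy set", {
  cohort <- default_cohort(5000, 101)
  specs <- build_builtin_scenarios(cohort, seed = 5)
  expect_length(specs, 4)
  expect_equal(specs$s1_universal_ear$uptake, 0.75)
  expect_equal(specs$s2_targeted_deprivation$percent, 0.213)
  expect_equal(specs$s2_targeted_deprivation$uptake, 0.75)
  expect_equal(specs$s3_indicated_prior_obesity$uptake, 1)
  expect_equal(specs$s3_indicated_prior_obesity$percent, 0.213)
  expect_equal(specs$s4_cap_at_ear$eligibility, "above_ear")
  expect_true(all(vapply(specs, function(s) s$lower_bound, TRUE)))

  # S1 jitter scales with the sex-specific reductions it delegates to
  med <- c(male = median(cohort$intake_kcal[cohort$sex == "male"]),
           female = median(cohort$intake_kcal[cohort$sex == "female"]))
  red <- compute_universal_reduction(med, c(male = 1171, female = 1076),
                                     mean(cohort$sex == "male"))
  expect_equal(unname(specs$s1_universal_ear$variability_sd),
               0.25 * red$absolute_reduction)
})
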