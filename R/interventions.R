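# Counterfactual calorie-reduction intervention scenarios: declarative
# specs, their application to the mediator (daily energy intake), and
# g-computation of post-intervention obesity prevalence and inequalities
# against the controlled-direct-effect reference model.

#' Declare an intervention scenario
#'
#' @param name Scenario label.
#' @param eligibility One of `"all"`, `"imd_high"` (area-deprivation score
#'   at least 1 SD above the cohort mean), `"obese_3y"` (prior obesity),
#'   `"above_ear"` (intake above the sex-specific estimated average
#'   requirement).
#' @param reduction One of `"shift_median_to_ear"` (sex-specific absolute
#'   reduction that moves the median to the EAR), `"percent"` (multiply
#'   intake by `1 - percent`), `"truncate_to_ear"` (cap intake at the
#'   sex-specific EAR).
#' @param percent Reduction fraction in [0, 1), required for the
#'   `"percent"` rule.
#' @param uptake Probability an eligible child receives the intervention.
#' @param variability_sd SD (kcal) of the mean-preserving normal jitter
#'   around the adjusted intake; scalar or named per-sex (`male`,
#'   `female`); 0 = deterministic. Ignored by `"truncate_to_ear"`.
#' @param lower_bound Apply the floor at 2 SD below the cohort mean intake
#'   (default `TRUE`; a child is never moved below the floor, and a child
#'   already below it is left unchanged).
#' @param seed Seed for the uptake and jitter draws.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(name,
                          eligibility = c("all", "imd_high", "obese_3y",
                                          "above_ear"),
                          reduction = c("shift_median_to_ear", "percent",
                                        "truncate_to_ear"),
                          percent = NULL, uptake = 1,
                          variability_sd = 0, lower_bound = TRUE,
                          seed = 1L) {
  eligibility <- match.arg(eligibility)
  reduction <- match.arg(reduction)
  assert_prob(uptake, "uptake")
  if (any(variability_sd < 0)) {
    abort("`variability_sd` must be >= 0.", class = "kcalmsm_param_error")
  }
  if (reduction == "percent") {
    if (is.null(percent) || percent < 0 || percent >= 1) {
      abort("`percent` must be in [0, 1) for the percent rule.",
            class = "kcalmsm_param_error")
    }
  }
  structure(list(name = name, eligibility = eligibility,
                 reduction = reduction, percent = percent, uptake = uptake,
                 variability_sd = variability_sd,
                 lower_bound = isTRUE(lower_bound), seed = seed),
            class = "scenario_spec")
}

#' Universal calorie reduction needed to bring medians to the EAR
#'
#' @param median_by_sex Named (male, female) observed median intakes, kcal.
#' @param ear_by_sex Named (male, female) EAR constants, kcal.
#' @param male_fraction Fraction of boys, used for the sex-weighted overall
#'   percentage reduction.
#' @return A `universal_reduction` object: tibble with one row per sex
#'   (`median_intake`, `ear`, `absolute_reduction`, `percent_reduction` as
#'   a fraction) and attribute `overall_percent`.
#' @export
#' @examples
#' r <- compute_universal_reduction(c(male = 1311.5, female = 1273.5),
#'                                  c(male = 1171.0, female = 1076.0), 0.513)
#' r
compute_universal_reduction <- function(median_by_sex, ear_by_sex,
                                        male_fraction) {
  if (any(median_by_sex <= 0) || any(ear_by_sex <= 0)) {
    abort("Medians and EARs must be positive.", class = "kcalmsm_param_error")
  }
  assert_prob(male_fraction, "male_fraction")
  sexes <- c("male", "female")
  med <- median_by_sex[sexes]
  ear <- ear_by_sex[sexes]
  absolute <- pmax(med - ear, 0)
  pct <- absolute / med
  out <- tibble::tibble(sex = sexes, median_intake = unname(med),
                        ear = unname(ear),
                        absolute_reduction = unname(absolute),
                        percent_reduction = unname(pct))
  attr(out, "overall_percent") <-
    unname(male_fraction * pct[["male"]] + (1 - male_fraction) * pct[["female"]])
  class(out) <- c("universal_reduction", class(out))
  out
}

#' @export
print.universal_reduction <- function(x, ...) {
  NextMethod()
  cat(sprintf("Sex-weighted overall reduction: %.1f%%\n",
              100 * attr(x, "overall_percent")))
  invisible(x)
}

#' Eligibility and uptake for a scenario
#'
#' @param cohort Cohort tibble.
#' @param spec A [scenario_spec()].
#' @param ear_table EAR table (needed for `"above_ear"` eligibility).
#' @return A tibble with logical columns `eligible` and `treated`
#'   (treated = eligible children passing an independent Bernoulli(uptake)
#'   draw under the scenario seed).
#' @export
select_eligible <- function(cohort, spec, ear_table = ear_reference()) {
  stopifnot(inherits(spec, "scenario_spec"))
  eligible <- switch(spec$eligibility,
    all = rep(TRUE, nrow(cohort)),
    imd_high = {
      assert_cols(cohort, "imd_score")
      if (anyNA(cohort$imd_score)) abort("`imd_score` has missing values.",
                                         class = "kcalmsm_fit_error")
      cohort$imd_score >= mean(cohort$imd_score) + sd(cohort$imd_score)
    },
    obese_3y = {
      assert_cols(cohort, "obese_3y")
      if (anyNA(cohort$obese_3y)) abort("`obese_3y` has missing values.",
                                        class = "kcalmsm_fit_error")
      cohort$obese_3y
    },
    above_ear = {
      assert_cols(cohort, c("intake_kcal", "sex"))
      cohort$intake_kcal > ear_lookup(cohort$sex, 3, ear_table)
    })
  set.seed(derive_seed(spec$seed, 0))
  treated <- eligible & (runif(nrow(cohort)) < spec$uptake)
  tibble::tibble(eligible = eligible, treated = treated)
}

#' Apply a calorie-reduction scenario to a cohort
#'
#' Reduces the daily energy intake of treated children per the scenario's
#' reduction rule, with optional mean-preserving normal jitter, then
#' enforces two guarantees: no child's intake ever increases, and (when
#' `lower_bound` is on) no child is moved below the floor of 2 SD below the
#' cohort's observed mean intake — children already below the floor are
#' left unchanged.
#'
#' @inheritParams select_eligible
#' @return A `scenario_application`: list with `cohort` (intake replaced),
#'   `eligible`, `treated`, `lower_bound` (kcal, or `-Inf`), `reduction`
#'   (a [compute_universal_reduction()] table for the shift rule).
#' @export
apply_scenario <- function(cohort, spec, ear_table = ear_reference()) {
  stopifnot(inherits(spec, "scenario_spec"))
  assert_cols(cohort, c("intake_kcal", "sex"))
  if (anyNA(cohort$intake_kcal)) {
    abort("`intake_kcal` must be complete (impute first).",
          class = "kcalmsm_fit_error")
  }
  masks <- select_eligible(cohort, spec, ear_table)
  treated <- masks$treated
  intake <- cohort$intake_kcal
  sex <- as.character(cohort$sex)
  bound <- if (spec$lower_bound) mean(intake) - 2 * sd(intake) else -Inf
  ear_by_sex <- c(male = ear_lookup("male", 3, ear_table),
                  female = ear_lookup("female", 3, ear_table))

  jitter_sd <- function(s) {
    v <- spec$variability_sd
    if (length(v) == 1L) unname(v) else unname(v[[s]])
  }
  # mean-preserving jitter within treated children of one sex
  recentred_jitter <- function(idx, s) {
    sdv <- jitter_sd(s)
    if (sdv == 0 || !length(idx)) return(numeric(length(idx)))
    e <- rnorm(length(idx), 0, sdv)
    e - mean(e)
  }

  candidate <- intake
  reduction_info <- NULL
  set.seed(derive_seed(spec$seed, 1))
  if (spec$reduction == "shift_median_to_ear") {
    med <- c(male = median(intake[sex == "male"]),
             female = median(intake[sex == "female"]))
    reduction_info <- compute_universal_reduction(med, ear_by_sex,
                                                  mean(sex == "male"))
    for (s in c("male", "female")) {
      idx <- which(treated & sex == s)
      red <- reduction_info$absolute_reduction[reduction_info$sex == s]
      candidate[idx] <- intake[idx] - (red + recentred_jitter(idx, s))
    }
  } else if (spec$reduction == "percent") {
    for (s in c("male", "female")) {
      idx <- which(treated & sex == s)
      candidate[idx] <- intake[idx] * (1 - spec$percent) +
        recentred_jitter(idx, s)
    }
  } else { # truncate_to_ear: deterministic cap
    idx <- which(treated)
    candidate[idx] <- pmin(intake[idx], ear_by_sex[sex[idx]])
  }

  n_below_zero <- sum(candidate[treated] < 0)
  if (n_below_zero > 0.01 * max(sum(treated), 1)) {
    warn(sprintf("Jitter pushed %d treated intake draws below zero before flooring.",
                 n_below_zero))
  }
  new_intake <- intake
  already_below <- intake < bound
  adj <- treated & !already_below
  new_intake[adj] <- pmax(pmin(candidate[adj], intake[adj]), bound)

  out <- cohort
  out$intake_kcal <- new_intake
  structure(list(cohort = out, eligible = masks$eligible, treated = treated,
                 lower_bound = bound, reduction = reduction_info,
                 spec = spec),
            class = "scenario_application")
}

#' Proportion of children consuming at or below the EAR
#'
#' @inheritParams select_eligible
#' @return A tibble with columns `sex` and `proportion` (fraction with
#'   intake less than or equal to the sex-specific EAR; `NA` for an empty
#'   stratum).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_children = 2000, seed = 5))
#' proportion_at_or_below_ear(cohort)
proportion_at_or_below_ear <- function(cohort, ear_table = ear_reference()) {
  assert_cols(cohort, c("intake_kcal", "sex"))
  purrr::map_dfr(c("male", "female"), function(s) {
    intake <- cohort$intake_kcal[cohort$sex == s]
    tibble::tibble(sex = s,
                   proportion = if (length(intake))
                     mean(intake <= ear_lookup(s, 3, ear_table))
                   else NA_real_)
  })
}

#' Simulate the impact of a scenario against the CDE reference
#'
#' Applies the scenario to the cohort's energy intake and g-computes
#' post-intervention obesity prevalence from the already-fitted CDE model
#' (the model is not refitted): per-child predicted probabilities with the
#' modified intake, averaged overall and within education groups, with
#' percent change against the CDE report, inequality metrics from the
#' continuous-coded companion fit, and pre/post proportions at or below
#' the EAR.
#'
#' @inheritParams select_eligible
#' @param cde A `cde_estimate` from [estimate_cde()] fitted on `cohort`.
#' @return An `intervention_result`: list with `name`, `cohort` (modified),
#'   `treated_fraction`, `eligible_fraction`, `ear_proportions` (pre/post
#'   by sex), `prevalence` (with `pct_change_vs_cde`), `inequality`,
#'   `lower_bound`.
#' @export
simulate_impact <- function(cohort, spec, cde, ear_table = ear_reference()) {
  stopifnot(inherits(cde, "cde_estimate"))
  needed <- setdiff(all.vars(cde$fit_cat$formula), "obese_6y")
  assert_cols(cohort, needed, what = "cohort (CDE model schema)")
  app <- apply_scenario(cohort, spec, ear_table)
  mod <- app$cohort
  prevalence <- build_prevalence_report(cde$fit_cat, mod, spec$name)
  ref <- cde$prevalence$estimate[match(prevalence$group,
                                       cde$prevalence$group)]
  prevalence$pct_change_vs_cde <- 100 * (prevalence$estimate - ref) / ref
  inequality <- inequality_metrics(cde$fit_cont, mod)
  ear_prop <- dplyr::bind_rows(
    pre = proportion_at_or_below_ear(cohort, ear_table),
    post = proportion_at_or_below_ear(mod, ear_table),
    .id = "when")
  structure(list(name = spec$name, spec = spec, cohort = mod,
                 eligible_fraction = mean(app$eligible),
                 treated_fraction = mean(app$treated),
                 ear_proportions = ear_prop,
                 prevalence = prevalence, inequality = inequality,
                 lower_bound = app$lower_bound,
                 reduction = app$reduction),
            class = "intervention_result")
}

#' @method tidy intervention_result
#' @export
tidy.intervention_result <- function(x, ...) x$prevalence

#' @method glance intervention_result
#' @export
glance.intervention_result <- function(x, ...) {
  prev <- x$prevalence
  ov <- prev[prev$group == "overall", ]
  post <- x$ear_proportions[x$ear_proportions$when == "post", ]
  dplyr::bind_cols(
    tibble::tibble(model_tag = x$name,
                   ear_boys = post$proportion[post$sex == "male"],
                   ear_girls = post$proportion[post$sex == "female"],
                   treated_fraction = x$treated_fraction,
                   overall = ov$estimate,
                   pct_change_overall = ov$pct_change_vs_cde),
    x$inequality[c("rr", "rr_lo", "rr_hi", "rd", "rd_lo", "rd_hi")])
}

#' @export
print.intervention_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %.1f%% eligible, %.1f%% treated\n",
              x$name, 100 * x$eligible_fraction, 100 * x$treated_fraction))
  print(x$prevalence)
  print(x$inequality)
  invisible(x)
}

#' The four built-in intervention scenarios
#'
#' Constructs the standard scenario set: (1) universal shift of median
#' intake to the EAR, 75% uptake, jitter SD defaulting to 25% of the
#' sex-specific absolute reduction; (2) 21.3% reduction targeted at
#' children from highly deprived areas (score at least 1 SD above the
#' cohort mean), 75% uptake; (3) 21.3% reduction indicated by obesity at
#' age 3, 100% uptake; (4) intake capped at the sex-specific EAR for
#' children consuming above it, 100% uptake. The lower-bound floor is on
#' for all four.
#'
#' @inheritParams select_eligible
#' @param seed Master seed; scenario k draws uptake/jitter under
#'   `derive_seed(seed, 10 + k)`.
#' @return A named list of four [scenario_spec()] objects.
#' @export
build_builtin_scenarios <- function(cohort, ear_table = ear_reference(),
                                    seed = 1L) {
  assert_cols(cohort, c("intake_kcal", "sex"))
  intake <- cohort$intake_kcal
  sex <- as.character(cohort$sex)
  med <- c(male = median(intake[sex == "male"]),
           female = median(intake[sex == "female"]))
  ear <- c(male = ear_lookup("male", 3, ear_table),
           female = ear_lookup("female", 3, ear_table))
  red <- compute_universal_reduction(med, ear, mean(sex == "male"))
  s1_sd <- setNames(0.25 * red$absolute_reduction, red$sex)
  intensive_sd <- 0.25 * 0.213 * median(intake)
  list(
    s1_universal_ear = scenario_spec(
      "s1_universal_ear", "all", "shift_median_to_ear", uptake = 0.75,
      variability_sd = s1_sd, seed = derive_seed(seed, 11)),
    s2_targeted_deprivation = scenario_spec(
      "s2_targeted_deprivation", "imd_high", "percent", percent = 0.213,
      uptake = 0.75, variability_sd = intensive_sd,
      seed = derive_seed(seed, 12)),
    s3_indicated_prior_obesity = scenario_spec(
      "s3_indicated_prior_obesity", "obese_3y", "percent", percent = 0.213,
      uptake = 1, variability_sd = intensive_sd,
      seed = derive_seed(seed, 13)),
    s4_cap_at_ear = scenario_spec(
      "s4_cap_at_ear", "above_ear", "truncate_to_ear", uptake = 1,
      variability_sd = 0, seed = derive_seed(seed, 14))
  )
}
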