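# Synthetic-cohort generator: child-level records drawn from a structural
# causal model ordered as ethnicity -> education -> intermediate confounders
# and deprivation -> energy intake -> obesity at 3y -> obesity at 6-7y.

# Draw everything upstream of the binary obesity outcomes. Shared between
# generate_cohort() and calibrate_logit_intercept().
simulate_structural_covariates <- function(p) {
  n <- as.integer(p$n_children)
  set.seed(p$seed)
  sex <- factor(ifelse(runif(n) < p$male_fraction, "male", "female"),
                levels = SEX_LEVELS)
  ethnicity <- factor(ifelse(runif(n) < p$ethnicity_white_prob,
                             "white", "non_white"), levels = ETH_LEVELS)

  # education | ethnicity: multinomial logit, base = marginal distribution
  base_logit <- log(p$education_probs[EDU_LEVELS])
  logits <- matrix(base_logit, nrow = n, ncol = 3, byrow = TRUE,
                   dimnames = list(NULL, EDU_LEVELS))
  nw <- ethnicity == "non_white"
  shift <- p$confounder_coefs$education_on_nonwhite
  logits[nw, "low"] <- logits[nw, "low"] + shift[["low"]]
  logits[nw, "high"] <- logits[nw, "high"] + shift[["high"]]
  education <- draw_categorical(softmax_rows(logits), EDU_LEVELS)
  code <- edu_code(education)
  code_c <- code - sum(p$education_probs[EDU_LEVELS] * c(2, 1, 0))

  cc <- p$confounder_coefs
  cm <- p$confounder_margins
  birthweight_cat <- draw_shifted_cat3(n, cm$birthweight, "low",
                                       cc$birthweight_low_per_level * code_c)
  health <- factor(ifelse(
    runif(n) < plogis(qlogis(cm$health_fairbad) +
                        cc$health_fairbad_per_level * code_c),
    "fair_bad", "good"), levels = HEALTH_LEVELS)
  activity_cat <- draw_shifted_cat3(n, cm$activity, "low",
                                    cc$activity_low_per_level * code_c)
  tv_cat <- draw_shifted_cat3(n, cm$tv, "high",
                              cc$tv_high_per_level * code_c)

  # area deprivation: standardized score, higher = more deprived
  imd_score <- cc$imd_per_level * code_c + rnorm(n)
  imd_quintile <- as.integer(cut(imd_score,
                                 breaks = quantile(imd_score, probs = seq(0, 1, 0.2),
                                                   names = FALSE),
                                 labels = FALSE, include.lowest = TRUE))

  im <- p$intake_model
  ce <- im$confounder_effects
  log_intake <- log(im$median_kcal[as.character(sex)]) +
    im$education_effect * code_c +
    ce[["bw_high"]] * (birthweight_cat == "high") +
    ce[["health_fairbad"]] * (health == "fair_bad") +
    ce[["activity_low"]] * (activity_cat == "low") +
    ce[["tv_high"]] * (tv_cat == "high") +
    ce[["nonwhite"]] * (ethnicity == "non_white") +
    rnorm(n, 0, im$log_sd[as.character(sex)])
  intake_kcal <- unname(exp(log_intake))

  tibble::tibble(
    id = seq_len(n), sex = sex, ethnicity = ethnicity, education = education,
    birthweight_cat = birthweight_cat, health = health,
    activity_cat = activity_cat, tv_cat = tv_cat,
    imd_score = imd_score, imd_quintile = imd_quintile,
    intake_kcal = intake_kcal
  )
}

# 3-category draw with a logit shift applied to one category.
draw_shifted_cat3 <- function(n, base_probs, shifted, shift_vec) {
  logits <- matrix(log(base_probs[CAT3_LEVELS]), nrow = n, ncol = 3,
                   byrow = TRUE, dimnames = list(NULL, CAT3_LEVELS))
  logits[, shifted] <- logits[, shifted] + shift_vec
  draw_categorical(softmax_rows(logits), CAT3_LEVELS)
}

# Logit-scale linear predictor of an outcome/prior-obesity model spec,
# excluding (or including) its intercept.
structural_linear_predictor <- function(covs, spec, intercept = spec$intercept) {
  ec <- spec$education_coef
  cf <- spec$confounder_coefs
  intercept +
    ec[["mid"]] * (covs$education == "mid") +
    ec[["low"]] * (covs$education == "low") +
    spec$intake_coef * covs$intake_kcal / 100 +
    cf[["nonwhite"]] * (covs$ethnicity == "non_white") +
    cf[["bw_low"]] * (covs$birthweight_cat == "low") +
    cf[["bw_high"]] * (covs$birthweight_cat == "high") +
    cf[["health_fairbad"]] * (covs$health == "fair_bad") +
    cf[["activity_low"]] * (covs$activity_cat == "low") +
    cf[["activity_high"]] * (covs$activity_cat == "high") +
    cf[["tv_low"]] * (covs$tv_cat == "low") +
    cf[["tv_high"]] * (covs$tv_cat == "high")
}

#' Generate a synthetic child cohort
#'
#' Simulates one row per child from the structural causal model described in
#' [cohort_params()]: baseline ethnicity, maternal education given
#' ethnicity, intermediate confounders (birthweight category, general
#' health, moderate activity, TV time) and area deprivation given education
#' and ethnicity, log-normal daily energy intake at age 3, obesity at age 3,
#' and obesity at age 6-7 years given education, intake and confounders.
#' Obesity flags are Bernoulli draws from the logistic structural model, so
#' the logit-scale coefficients in `params` are the ground truth that a
#' correctly specified marginal structural model should recover; BMI
#' z-scores are drawn consistently with each flag (standard normal truncated
#' at the 95th-centile cut-off 1.6449).
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per child and columns `id`, `sex`,
#'   `ethnicity`, `education`, `birthweight_cat`, `health`, `activity_cat`,
#'   `tv_cat`, `imd_score`, `imd_quintile`, `intake_kcal`, `bmi_z_3y`,
#'   `obese_3y`, `bmi_z_6y`, `obese_6y`. The generating parameters (the
#'   ground truth) are attached as attribute `"truth"`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_children = 1000, seed = 42))
#' dplyr::count(cohort, education)
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, params)
  }
  validate_cohort_params(params)
  covs <- simulate_structural_covariates(params)
  n <- nrow(covs)
  z_cut <- OBESE_Z_CUTOFF

  p3 <- plogis(structural_linear_predictor(covs, params$prior_obesity_model))
  obese_3y <- runif(n) < p3
  bmi_z_3y <- numeric(n)
  bmi_z_3y[obese_3y] <- rtruncnorm_std(sum(obese_3y), z_cut, "upper")
  bmi_z_3y[!obese_3y] <- rtruncnorm_std(sum(!obese_3y), z_cut, "lower")

  p6 <- plogis(structural_linear_predictor(covs, params$outcome_model))
  obese_6y <- runif(n) < p6
  bmi_z_6y <- numeric(n)
  bmi_z_6y[obese_6y] <- rtruncnorm_std(sum(obese_6y), z_cut, "upper")
  bmi_z_6y[!obese_6y] <- rtruncnorm_std(sum(!obese_6y), z_cut, "lower")

  cohort <- dplyr::mutate(covs,
                          bmi_z_3y = bmi_z_3y, obese_3y = obese_3y,
                          bmi_z_6y = bmi_z_6y, obese_6y = obese_6y)
  attr(cohort, "truth") <- params
  cohort
}

#' Mask cohort values to emulate attrition and item non-response
#'
#' Applies Bernoulli missingness to selected columns, either completely at
#' random (MCAR) or at random given maternal education (MAR), where the odds
#' of missingness are multiplied by `education_or` per disadvantage level
#' (high = 0, mid = 1, low = 2). The exposure (`education`) and the outcome
#' (`bmi_z_6y`, `obese_6y`) can never be masked: the analytic sample is, by
#' construction, complete on both.
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param spec A [missingness_spec()].
#' @return The cohort with masked entries set to `NA`.
#' @export
impose_missingness <- function(cohort, spec) {
  stopifnot(inherits(spec, "missingness_spec"))
  protected <- c("id", "education", "bmi_z_6y", "obese_6y")
  bad <- intersect(names(spec$probs), protected)
  if (length(bad)) {
    abort(sprintf("Exposure/outcome columns cannot be masked: %s",
                  paste(bad, collapse = ", ")),
          class = "kcalmsm_param_error")
  }
  assert_cols(cohort, names(spec$probs))
  set.seed(spec$seed)
  out <- cohort
  code <- edu_code(cohort$education)
  for (col in names(spec$probs)) {
    p <- spec$probs[[col]]
    p_i <- if (spec$mechanism == "MCAR") rep(p, nrow(cohort)) else
      plogis(qlogis(p) + log(spec$education_or) * code)
    out[[col]][runif(nrow(cohort)) < p_i] <- NA
  }
  attr(out, "truth") <- attr(cohort, "truth")
  out
}

#' @rdname impose_missingness
#' @param probs Named vector of per-column missingness probabilities in [0,1).
#' @param mechanism `"MCAR"` or `"MAR_education"`.
#' @param education_or Odds multiplier of missingness per disadvantage level
#'   (only used under `"MAR_education"`; the stated probability applies to
#'   the high-education group).
#' @param seed Integer seed for the masking draws.
#' @export
missingness_spec <- function(probs, mechanism = c("MCAR", "MAR_education"),
                             education_or = 1.5, seed = 1L) {
  mechanism <- match.arg(mechanism)
  assert_prob(unlist(probs), "probs", open_upper = TRUE)
  if (is.null(names(probs)) || any(!nzchar(names(probs)))) {
    abort("`probs` must be a named vector of column probabilities.",
          class = "kcalmsm_param_error")
  }
  structure(list(probs = as.list(probs), mechanism = mechanism,
                 education_or = education_or, seed = seed),
            class = "missingness_spec")
}

COHORT_COLS <- c("id", "sex", "ethnicity", "education", "birthweight_cat",
                 "health", "activity_cat", "tv_cat", "imd_score",
                 "imd_quintile", "intake_kcal", "bmi_z_3y", "obese_3y",
                 "bmi_z_6y", "obese_6y")

#' Write or read a cohort table
#'
#' Cohorts are stored as comma-delimited text with a header, one row per
#' child and an empty cell for a missing value. `write_cohort()` also writes
#' a JSON sidecar (`<path>.meta.json`) recording the generating parameters,
#' when present, so ground-truth coefficients travel with the data.
#' `read_cohort()` validates labels and ranges and restores column types.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cols(cohort, COHORT_COLS)
  readr::write_csv(cohort[COHORT_COLS], path, na = "")
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(
                           id = readr::col_integer(),
                           sex = readr::col_character(),
                           ethnicity = readr::col_character(),
                           education = readr::col_character(),
                           birthweight_cat = readr::col_character(),
                           health = readr::col_character(),
                           activity_cat = readr::col_character(),
                           tv_cat = readr::col_character(),
                           imd_score = readr::col_double(),
                           imd_quintile = readr::col_integer(),
                           intake_kcal = readr::col_double(),
                           bmi_z_3y = readr::col_double(),
                           obese_3y = readr::col_logical(),
                           bmi_z_6y = readr::col_double(),
                           obese_6y = readr::col_logical()
                         ))
  assert_cols(raw, COHORT_COLS, what = sprintf("cohort file '%s'", path))
  check_labels <- function(col, levels) {
    vals <- raw[[col]]
    bad <- which(!is.na(vals) & !(vals %in% levels))
    if (length(bad)) {
      abort(sprintf("Column '%s' of '%s' has unknown label '%s' (row %d).",
                    col, path, vals[bad[1]], bad[1]),
            class = "kcalmsm_parse_error")
    }
    factor(vals, levels = levels)
  }
  out <- dplyr::mutate(raw,
    sex = check_labels("sex", SEX_LEVELS),
    ethnicity = check_labels("ethnicity", ETH_LEVELS),
    education = check_labels("education", EDU_LEVELS),
    birthweight_cat = check_labels("birthweight_cat", CAT3_LEVELS),
    health = check_labels("health", HEALTH_LEVELS),
    activity_cat = check_labels("activity_cat", CAT3_LEVELS),
    tv_cat = check_labels("tv_cat", CAT3_LEVELS)
  )
  bad_intake <- which(!is.na(out$intake_kcal) & out$intake_kcal <= 0)
  if (length(bad_intake)) {
    abort(sprintf("Column 'intake_kcal' of '%s' must be positive (row %d).",
                  path, bad_intake[1]),
          class = "kcalmsm_parse_error")
  }
  if (anyDuplicated(out$id)) {
    abort(sprintf("Column 'id' of '%s' has duplicated identifiers.", path),
          class = "kcalmsm_parse_error")
  }
  meta <- paste0(path, ".meta.json")
  if (file.exists(meta)) {
    restore <- function(x) {
      if (!is.list(x)) return(x)
      scalar <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, TRUE)
      if (all(scalar)) unlist(x) else lapply(x, restore)
    }
    truth <- restore(jsonlite::read_json(meta))
    attr(out, "truth") <- structure(truth, class = "cohort_params")
  }
  out
}
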