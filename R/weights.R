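# Stabilized inverse-probability weights for the exposure (3-level maternal
# education) and the continuous mediator (daily energy intake), their
# product, and percentile truncation.

#' Stabilized exposure weights
#'
#' Computes per-child stabilized inverse-probability-of-exposure weights
#' P(A = a_i) / P(A = a_i | C_i): the denominator from a 3-category
#' multinomial logistic regression of maternal education on the baseline
#' confounder (child ethnicity), the numerator from the marginal education
#' distribution.
#'
#' @param cohort Cohort tibble with complete `education` and `ethnicity`.
#' @return Numeric vector of positive weights, one per child.
#' @export
fit_exposure_weights <- function(cohort) {
  assert_cols(cohort, c("education", "ethnicity"))
  if (anyNA(cohort$education) || anyNA(cohort$ethnicity)) {
    abort("`education` and `ethnicity` must be complete for exposure weights.",
          class = "kcalmsm_fit_error")
  }
  edu <- factor(cohort$education, levels = EDU_LEVELS)
  fit <- tryCatch(
    nnet::multinom(edu ~ ethnicity, data = cohort, trace = FALSE,
                   maxit = 200),
    error = function(e) abort(paste0("Exposure model failed to fit: ",
                                     conditionMessage(e)),
                              class = "kcalmsm_fit_error")
  )
  if (fit$convergence != 0) {
    abort("Exposure multinomial model did not converge.",
          class = "kcalmsm_fit_error")
  }
  denom_probs <- predict(fit, newdata = cohort, type = "probs")
  if (is.null(dim(denom_probs))) denom_probs <- rbind(denom_probs)
  idx <- cbind(seq_len(nrow(cohort)), match(as.character(edu),
                                            colnames(denom_probs)))
  denom <- denom_probs[idx]
  num <- prop.table(table(edu))[as.character(edu)]
  w <- as.numeric(num) / denom
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("Exposure weights are not all positive and finite (separation?).",
          class = "kcalmsm_fit_error")
  }
  w
}

#' Stabilized mediator (energy-intake) weights
#'
#' Density-ratio weights f(M_i | A_i) / f(M_i | A_i, C_i, L_i) for the
#' continuous mediator, with both conditional densities normal on the
#' log-kcal scale: the numerator from a linear regression of log intake on
#' education (and sex, by default), the denominator adding the baseline
#' confounder (ethnicity) and the four intermediate confounders
#' (birthweight category, general health, moderate activity, TV time).
#' Residual variances are the maximum-likelihood estimates from each fit.
#'
#' @param cohort Cohort tibble; `intake_kcal`, `education`, `ethnicity`,
#'   `birthweight_cat`, `health`, `activity_cat`, `tv_cat` must be complete.
#' @param include_sex Include sex in both intake models (default `TRUE`;
#'   intakes are strongly sex-patterned).
#' @return Numeric vector of positive, finite weights.
#' @export
fit_mediator_weights <- function(cohort, include_sex = TRUE) {
  need <- c("intake_kcal", "education", "ethnicity", "birthweight_cat",
            "health", "activity_cat", "tv_cat")
  assert_cols(cohort, need)
  if (anyNA(cohort[need])) {
    abort("Mediator and confounders must be complete for mediator weights (impute first).",
          class = "kcalmsm_fit_error")
  }
  dat <- dplyr::mutate(cohort, .log_intake = log(.data$intake_kcal))
  sex_term <- if (include_sex) " + sex" else ""
  f_num <- as.formula(paste0(".log_intake ~ education", sex_term))
  f_den <- as.formula(paste0(
    ".log_intake ~ education + ethnicity + birthweight_cat + health + activity_cat + tv_cat",
    sex_term))
  fit_num <- lm(f_num, data = dat)
  fit_den <- lm(f_den, data = dat)
  n <- nrow(dat)
  sd_num <- sqrt(sum(fit_num$residuals^2) / n)
  sd_den <- sqrt(sum(fit_den$residuals^2) / n)
  if (sd_num < 1e-8 || sd_den < 1e-8) {
    abort("Zero residual variance in an intake model; mediator weights undefined.",
          class = "kcalmsm_fit_error")
  }
  w <- dnorm(dat$.log_intake, fitted(fit_num), sd_num) /
    dnorm(dat$.log_intake, fitted(fit_den), sd_den)
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("Mediator weights are not all positive and finite.",
          class = "kcalmsm_fit_error")
  }
  unname(w)
}

#' Percentile truncation of weights
#'
#' Caps weights at the empirical `lower_pct` and `upper_pct` percentiles of
#' the input vector (inverse-empirical-CDF quantiles, so the bounds are
#' order statistics of the input): values below the lower bound are set to
#' it, values above the upper bound are set to it, interior values are
#' unchanged.
#'
#' @param weights Positive weight vector.
#' @param lower_pct,upper_pct Percentiles in [0, 100]; defaults 1 and 99.
#' @return Truncated weights, with the bounds attached as attribute
#'   `"bounds"`.
#' @export
truncate_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  if (!length(weights)) {
    abort("Cannot truncate an empty weight vector.",
          class = "kcalmsm_param_error")
  }
  stopifnot(all(weights > 0), lower_pct >= 0, upper_pct <= 100,
            lower_pct <= upper_pct)
  bounds <- quantile(weights, c(lower_pct, upper_pct) / 100,
                     type = 1, names = FALSE)
  out <- pmin(pmax(weights, bounds[1]), bounds[2])
  attr(out, "bounds") <- c(lower = bounds[1], upper = bounds[2])
  out
}

#' Combine exposure and mediator weights
#'
#' Elementwise product of the two stabilized weight vectors.
#'
#' @param exposure_w,mediator_w Positive weight vectors of equal length.
#' @return The combined weight vector.
#' @export
combine_weights <- function(exposure_w, mediator_w) {
  if (length(exposure_w) != length(mediator_w)) {
    abort("Weight vectors must have equal length.",
          class = "kcalmsm_param_error")
  }
  stopifnot(all(exposure_w > 0), all(mediator_w > 0))
  exposure_w * mediator_w
}

#' Estimate the full inverse-probability weight set
#'
#' Convenience wrapper: exposure weights, mediator weights, their product,
#' and the percentile-truncated product, as one tibble with per-stage
#' diagnostics attached.
#'
#' @inheritParams fit_mediator_weights
#' @inheritParams truncate_weights
#' @return A tibble of class `ipw_set` with columns `exposure_weight`,
#'   `mediator_weight`, `combined_weight`, `truncated_weight`; diagnostics
#'   via [weight_diagnostics()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_children = 2000, seed = 3))
#' w <- estimate_ip_weights(cohort)
#' weight_diagnostics(w)
estimate_ip_weights <- function(cohort, include_sex = TRUE,
                                lower_pct = 1, upper_pct = 99) {
  ew <- fit_exposure_weights(cohort)
  mw <- fit_mediator_weights(cohort, include_sex = include_sex)
  cw <- combine_weights(ew, mw)
  tw <- truncate_weights(cw, lower_pct, upper_pct)
  out <- tibble::tibble(exposure_weight = ew, mediator_weight = mw,
                        combined_weight = cw,
                        truncated_weight = as.numeric(tw))
  attr(out, "bounds") <- attr(tw, "bounds")
  attr(out, "truncation_pct") <- c(lower = lower_pct, upper = upper_pct)
  class(out) <- c("ipw_set", class(out))
  out
}

#' Weight diagnostics table
#'
#' @param weights An `ipw_set` from [estimate_ip_weights()].
#' @return A tibble with one row per weight stage (mean, sd, min, 1st/99th
#'   percentiles, max) plus the truncation bounds.
#' @export
weight_diagnostics <- function(weights) {
  stopifnot(inherits(weights, "ipw_set"))
  smry <- function(w) {
    q <- quantile(w, c(0.01, 0.99), type = 1, names = FALSE)
    tibble::tibble(mean = mean(w), sd = sd(w), min = min(w),
                   p01 = q[1], p99 = q[2], max = max(w))
  }
  out <- dplyr::bind_rows(
    exposure = smry(weights$exposure_weight),
    mediator = smry(weights$mediator_weight),
    combined = smry(weights$combined_weight),
    truncated = smry(weights$truncated_weight),
    .id = "stage"
  )
  bounds <- attr(weights, "bounds")
  out$truncation_lower <- bounds[["lower"]]
  out$truncation_upper <- bounds[["upper"]]
  out
}
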