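# Unadjusted and controlled-direct-effect (CDE) prevalence estimates with
# inequality metrics (risk ratio, risk difference) and their CIs.

add_edu_code <- function(cohort) {
  dplyr::mutate(cohort, edu_code = edu_code(.data$education))
}

# Delta-method variance of group-averaged predicted probabilities.
# rows: list of logical index vectors; returns tibble(estimate, se).
averaged_prob_and_se <- function(fit, newdata, rows) {
  X <- model.matrix(stats::delete.response(stats::terms(fit$glm)),
                    data = newdata, xlev = fit$glm$xlevels)
  p <- as.numeric(plogis(X %*% fit$coefficients))
  purrr::map_dfr(rows, function(idx) {
    est <- mean(p[idx])
    grad <- colMeans(X[idx, , drop = FALSE] * (p[idx] * (1 - p[idx])))
    tibble::tibble(estimate = est,
                   se = sqrt(drop(t(grad) %*% fit$vcov %*% grad)))
  })
}

build_prevalence_report <- function(fit, cohort, model_tag,
                                    conf_level = 0.95) {
  zq <- qnorm(1 - (1 - conf_level) / 2)
  groups <- list(overall = rep(TRUE, nrow(cohort)),
                 low = cohort$education == "low",
                 mid = cohort$education == "mid",
                 high = cohort$education == "high")
  empty <- vapply(groups, function(g) !any(g), TRUE)
  if (any(empty)) {
    abort(sprintf("Empty education group(s): %s",
                  paste(names(groups)[empty], collapse = ", ")),
          class = "kcalmsm_fit_error")
  }
  res <- averaged_prob_and_se(fit, cohort, groups)
  tibble::tibble(
    model_tag = model_tag, group = names(groups),
    estimate = res$estimate,
    conf.low = pmax(0, res$estimate - zq * res$se),
    conf.high = pmin(1, res$estimate + zq * res$se)
  )
}

# G-computation of p_hat at extreme education codes from a continuous-coded
# fit: average over all children of the fitted probability with the code
# set to 2 (low) or 0 (high), other covariates at observed values.
gcomp_extreme_probs <- function(fit_cont, cohort) {
  dat <- add_edu_code(cohort)
  p_at <- function(code) {
    dat$edu_code <- code
    mean(predict_prob(fit_cont, dat))
  }
  c(low = p_at(2), high = p_at(0))
}

#' Inequality metrics from a fitted MSM
#'
#' Risk ratio and risk difference comparing the lowest to the highest
#' maternal-education group, with education entered as a continuous linear
#' term (disadvantage-coded high = 0, mid = 1, low = 2, so RR > 1 means
#' excess risk with disadvantage). Fitted probabilities are g-computed at
#' the extreme codes, averaging over the sample's other covariates. If
#' `fit` used categorical education it is refitted with the continuous
#' code, reusing its weights. CIs here are delta-method; the
#' `estimate_*()` functions additionally offer a nonparametric bootstrap
#' that resamples children before weight estimation.
#'
#' @param fit An `msm_fit`.
#' @param cohort The cohort the fit pertains to.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row: `rr`, `rr_lo`, `rr_hi`, `rd`, `rd_lo`,
#'   `rd_hi` (risk difference in percentage points), `p_low`, `p_high`.
#' @export
inequality_metrics <- function(fit, cohort, conf_level = 0.95) {
  stopifnot(inherits(fit, "msm_fit"))
  if (fit$education_coding != "continuous_linear") {
    dat <- add_edu_code(cohort)
    new_formula <- as.formula(
      gsub("\\beducation\\b", "edu_code",
           paste(deparse(fit$formula), collapse = " ")))
    fit <- fit_weighted_logistic(dat, new_formula,
                                 weights = fit$glm$prior.weights,
                                 weight_source = fit$weight_source)
  }
  dat <- add_edu_code(cohort)
  X <- model.matrix(stats::delete.response(stats::terms(fit$glm)),
                    data = dat, xlev = fit$glm$xlevels)
  code_col <- which(colnames(X) == "edu_code")
  prob_grad <- function(code) {
    Xa <- X
    Xa[, code_col] <- code
    p <- as.numeric(plogis(Xa %*% fit$coefficients))
    list(p = mean(p), grad = colMeans(Xa * (p * (1 - p))))
  }
  lo <- prob_grad(2); hi <- prob_grad(0)
  if (hi$p <= 0) {
    abort("Fitted probability in the high-education group is zero; RR undefined.",
          class = "kcalmsm_fit_error")
  }
  rr <- lo$p / hi$p
  rd <- (lo$p - hi$p) * 100
  zq <- qnorm(1 - (1 - conf_level) / 2)
  g_logrr <- lo$grad / lo$p - hi$grad / hi$p
  se_logrr <- sqrt(drop(t(g_logrr) %*% fit$vcov %*% g_logrr))
  g_rd <- (lo$grad - hi$grad) * 100
  se_rd <- sqrt(drop(t(g_rd) %*% fit$vcov %*% g_rd))
  tibble::tibble(
    rr = rr, rr_lo = rr * exp(-zq * se_logrr), rr_hi = rr * exp(zq * se_logrr),
    rd = rd, rd_lo = rd - zq * se_rd, rd_hi = rd + zq * se_rd,
    p_low = lo$p, p_high = hi$p
  )
}

# Nonparametric bootstrap over children: refit_fun(resampled cohort) must
# return c(rr, rd). Returns percentile CI columns.
bootstrap_inequality <- function(cohort, refit_fun, point, boot_reps, seed,
                                 conf_level = 0.95) {
  set.seed(seed)
  n <- nrow(cohort)
  draws <- matrix(NA_real_, boot_reps, 2)
  for (b in seq_len(boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    draws[b, ] <- tryCatch(refit_fun(cohort[idx, , drop = FALSE]),
                           error = function(e) c(NA_real_, NA_real_))
  }
  ok <- complete.cases(draws)
  if (mean(ok) < 0.5) {
    abort("More than half of bootstrap replicates failed.",
          class = "kcalmsm_fit_error")
  }
  alpha <- (1 - conf_level) / 2
  ci <- apply(draws[ok, , drop = FALSE], 2, quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(rr = point[["rr"]], rr_lo = ci[1, 1], rr_hi = ci[2, 1],
                 rd = point[["rd"]], rd_lo = ci[1, 2], rd_hi = ci[2, 2],
                 p_low = point[["p_low"]], p_high = point[["p_high"]])
}

#' Unadjusted obesity prevalence and inequalities
#'
#' Logistic regression of obesity at 6-7 years on maternal education alone
#' (saturated in the three groups), predicted probabilities per group with
#' 95% confidence intervals, the overall observation-weighted mean, and
#' risk-ratio / risk-difference inequalities from a continuous-coded refit.
#'
#' @param cohort Cohort tibble; `education` and `obese_6y` must be complete.
#' @param ci_method `"bootstrap"` (nonparametric, over children) or
#'   `"delta"` for the inequality CIs; group-prevalence CIs are always
#'   delta-method.
#' @param boot_reps Bootstrap replicates (default 499).
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level.
#' @return A `msm_estimate` object: list with `prevalence` (tibble),
#'   `inequality` (tibble), `fit_cat`, `fit_cont`, `model_tag`.
#' @export
estimate_unadjusted <- function(cohort, ci_method = c("bootstrap", "delta"),
                                boot_reps = 499, seed = 1L,
                                conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  assert_cols(cohort, c("education", "obese_6y"))
  if (anyNA(cohort$education) || anyNA(cohort$obese_6y)) {
    abort("`education` and `obese_6y` must be complete.",
          class = "kcalmsm_fit_error")
  }
  fit_cat <- fit_weighted_logistic(cohort, obese_6y ~ education,
                                   weight_source = "unweighted")
  fit_cont <- fit_weighted_logistic(add_edu_code(cohort),
                                    obese_6y ~ edu_code,
                                    weight_source = "unweighted")
  prevalence <- build_prevalence_report(fit_cat, cohort, "unadjusted",
                                        conf_level)
  point <- inequality_metrics(fit_cont, cohort, conf_level)
  inequality <- if (ci_method == "delta") point else {
    refit <- function(boot) {
      f <- fit_weighted_logistic(add_edu_code(boot), obese_6y ~ edu_code,
                                 weight_source = "unweighted")
      m <- inequality_metrics(f, boot, conf_level)
      c(m$rr, m$rd)
    }
    bootstrap_inequality(cohort, refit, point, boot_reps, seed, conf_level)
  }
  structure(list(model_tag = "unadjusted", prevalence = prevalence,
                 inequality = inequality, fit_cat = fit_cat,
                 fit_cont = fit_cont, n = nrow(cohort)),
            class = c("unadjusted_estimate", "msm_estimate"))
}

#' Controlled direct effect of maternal education on obesity
#'
#' Fits the inverse-probability-weighted logistic marginal structural model
#' of obesity at 6-7 years on maternal education and daily energy intake
#' (continuous, scaled per 100 kcal), holding intake at its observed value.
#' Per-child predicted probabilities are averaged overall and within
#' education groups; inequalities come from a continuous-coded companion
#' fit via g-computation at the extreme education codes. This estimate is
#' the reference against which intervention scenarios are compared.
#'
#' @param cohort Cohort tibble with complete analysis columns.
#' @param weights An `ipw_set` from [estimate_ip_weights()], a positive
#'   numeric vector, or `NULL` to estimate weights from `cohort`.
#' @inheritParams estimate_unadjusted
#' @param include_sex Passed to [estimate_ip_weights()] when weights are
#'   estimated here (and re-estimated inside the bootstrap).
#' @return A `cde_estimate` object: list with `prevalence`, `inequality`,
#'   `fit_cat`, `fit_cont`, `weights`, `model_tag`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_children = 3000, seed = 11))
#' cde <- estimate_cde(cohort, ci_method = "delta")
#' tidy(cde)
#' glance(cde)
estimate_cde <- function(cohort, weights = NULL,
                         ci_method = c("bootstrap", "delta"),
                         boot_reps = 499, seed = 1L, conf_level = 0.95,
                         include_sex = TRUE) {
  ci_method <- match.arg(ci_method)
  assert_cols(cohort, c("education", "obese_6y", "intake_kcal"))
  if (anyNA(cohort$intake_kcal)) {
    abort("`intake_kcal` must be complete (impute first).",
          class = "kcalmsm_fit_error")
  }
  if (is.null(weights)) weights <- estimate_ip_weights(cohort, include_sex)
  w <- if (inherits(weights, "ipw_set")) weights$truncated_weight
  else as.numeric(weights)
  fit_cat <- fit_weighted_logistic(cohort,
                                   obese_6y ~ education + I(intake_kcal / 100),
                                   weights = w, weight_source = "ipw_truncated")
  fit_cont <- fit_weighted_logistic(add_edu_code(cohort),
                                    obese_6y ~ edu_code + I(intake_kcal / 100),
                                    weights = w, weight_source = "ipw_truncated")
  prevalence <- build_prevalence_report(fit_cat, cohort, "cde", conf_level)
  point <- inequality_metrics(fit_cont, cohort, conf_level)
  inequality <- if (ci_method == "delta") point else {
    refit <- function(boot) {
      wb <- estimate_ip_weights(boot, include_sex)$truncated_weight
      f <- fit_weighted_logistic(add_edu_code(boot),
                                 obese_6y ~ edu_code + I(intake_kcal / 100),
                                 weights = wb, weight_source = "ipw_truncated")
      m <- inequality_metrics(f, boot, conf_level)
      c(m$rr, m$rd)
    }
    bootstrap_inequality(cohort, refit, point, boot_reps, seed, conf_level)
  }
  structure(list(model_tag = "cde", prevalence = prevalence,
                 inequality = inequality, fit_cat = fit_cat,
                 fit_cont = fit_cont, weights = weights, n = nrow(cohort)),
            class = c("cde_estimate", "msm_estimate"))
}

#' @method tidy msm_estimate
#' @export
tidy.msm_estimate <- function(x, ...) x$prevalence

#' @method glance msm_estimate
#' @export
glance.msm_estimate <- function(x, ...) {
  overall <- x$prevalence$estimate[x$prevalence$group == "overall"]
  dplyr::bind_cols(tibble::tibble(model_tag = x$model_tag, n = x$n,
                                  overall = overall),
                   x$inequality[c("rr", "rr_lo", "rr_hi",
                                  "rd", "rd_lo", "rd_hi")])
}

#' @export
print.msm_estimate <- function(x, ...) {
  cat(sprintf("%s model (n = %d)\n", x$model_tag, x$n))
  print(x$prevalence)
  cat("Inequalities (low vs high education):\n")
  print(x$inequality)
  invisible(x)
}
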