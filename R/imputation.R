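# Multiple imputation by chained equations (lightweight, parametric) and
# Rubin's rules for pooling estimates across completed data sets.

#' Multiple imputation by chained equations
#'
#' Completes a cohort with missing mediator/confounder values by iterated
#' conditional models: a normal linear regression on the log scale for
#' energy intake, linear regression for other numeric columns, logistic
#' regression for 2-level factors and multinomial logistic regression for
#' 3-level factors, each conditioning on the other analysis variables
#' (always including the exposure and the outcome, which must be
#' complete). Predictive draws are parametric: linear-model coefficients
#' are drawn from their asymptotic normal distribution with a chi-square
#' residual-variance draw; categorical draws use plug-in fitted
#' probabilities. This is simpler than predictive mean matching and is
#' documented as such.
#'
#' @param cohort Cohort tibble; `education`, `obese_6y` complete.
#' @param m Number of completed data sets (m = 50 is supported; default 5).
#' @param seed Master seed; imputation k uses sub-seed
#'   `derive_seed(seed, k)`.
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @return An `imputation_set`: list with `imputations` (list of m complete
#'   tibbles), `seeds`, `m`, and `missing_cols`.
#' @export
chained_imputation <- function(cohort, m = 5, seed = 1L, cycles = 10) {
  stopifnot(m >= 1, cycles >= 1)
  if (anyNA(cohort$education) || anyNA(cohort$obese_6y)) {
    abort("Exposure and outcome must be complete before imputation.",
          class = "kcalmsm_fit_error")
  }
  candidate <- c("intake_kcal", "birthweight_cat", "health", "activity_cat",
                 "tv_cat", "imd_score", "bmi_z_3y", "obese_3y")
  candidate <- intersect(candidate, names(cohort))
  missing_cols <- candidate[vapply(candidate, function(cl) anyNA(cohort[[cl]]),
                                   TRUE)]
  frac_missing <- vapply(missing_cols, function(cl) mean(is.na(cohort[[cl]])),
                         numeric(1))
  if (any(frac_missing > 0.95)) {
    abort(sprintf("Column(s) with >95%% missing cannot be imputed: %s",
                  paste(missing_cols[frac_missing > 0.95], collapse = ", ")),
          class = "kcalmsm_fit_error")
  }
  if (!length(missing_cols)) {
    return(structure(list(imputations = replicate(m, cohort, simplify = FALSE),
                          seeds = vapply(seq_len(m), derive_seed,
                                         integer(1), master = seed),
                          m = m, missing_cols = character()),
                     class = "imputation_set"))
  }
  predictors <- setdiff(c("education", "obese_6y", "sex", candidate),
                        character())
  seeds <- vapply(seq_len(m), function(k) derive_seed(seed, k), integer(1))
  imputations <- lapply(seq_len(m), function(k) {
    set.seed(seeds[k])
    impute_once(cohort, missing_cols, predictors, cycles)
  })
  structure(list(imputations = imputations, seeds = seeds, m = m,
                 missing_cols = missing_cols),
            class = "imputation_set")
}

impute_once <- function(cohort, missing_cols, predictors, cycles) {
  dat <- cohort
  na_idx <- lapply(missing_cols, function(cl) which(is.na(dat[[cl]])))
  names(na_idx) <- missing_cols
  # initial fill: random draws from the observed margin
  for (cl in missing_cols) {
    obs <- dat[[cl]][!is.na(dat[[cl]])]
    dat[[cl]][na_idx[[cl]]] <- sample(obs, length(na_idx[[cl]]),
                                      replace = TRUE)
  }
  for (cyc in seq_len(cycles)) {
    for (cl in missing_cols) {
      idx <- na_idx[[cl]]
      rhs <- setdiff(predictors, cl)
      # imd_quintile is derived, never a predictor here
      rhs <- setdiff(rhs, "imd_quintile")
      dat[[cl]][idx] <- draw_conditional(dat, cl, rhs, idx,
                                         obs_rows = setdiff(seq_len(nrow(dat)), idx))
    }
  }
  if ("imd_score" %in% missing_cols && "imd_quintile" %in% names(dat)) {
    dat$imd_quintile <- as.integer(cut(dat$imd_score,
                                       quantile(dat$imd_score, seq(0, 1, 0.2),
                                                names = FALSE),
                                       labels = FALSE, include.lowest = TRUE))
  }
  if ("bmi_z_3y" %in% names(dat) && "obese_3y" %in% missing_cols) {
    # keep the flag consistent with the z-score where the z is observed
    known_z <- !is.na(cohort$bmi_z_3y)
    dat$obese_3y[known_z] <- dat$bmi_z_3y[known_z] > OBESE_Z_CUTOFF
  }
  dat
}

draw_conditional <- function(dat, target, rhs, idx, obs_rows) {
  fml <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit_dat <- dat
  y <- dat[[target]]
  if (target == "intake_kcal") {
    fit_dat$.y <- log(y)
    draws <- draw_lm(fit_dat, fml, obs_rows, idx)
    return(exp(draws))
  }
  if (is.numeric(y)) {
    fit_dat$.y <- y
    return(draw_lm(fit_dat, fml, obs_rows, idx))
  }
  if (is.logical(y) || (is.factor(y) && nlevels(y) == 2L)) {
    lv <- if (is.factor(y)) levels(y) else c(FALSE, TRUE)
    fit_dat$.y <- if (is.factor(y)) y == lv[2] else y
    f <- glm(fml, family = binomial(), data = fit_dat[obs_rows, ])
    p <- predict(f, newdata = fit_dat[idx, ], type = "response")
    hit <- runif(length(idx)) < p
    return(if (is.factor(y)) as.character(ifelse(hit, lv[2], lv[1])) else hit)
  }
  fit_dat$.y <- factor(y)
  f <- nnet::multinom(fml, data = fit_dat[obs_rows, ], trace = FALSE)
  p <- predict(f, newdata = fit_dat[idx, ], type = "probs")
  if (is.null(dim(p))) p <- rbind(p) # single row to impute
  as.character(draw_categorical(p, colnames(p)))
}

# Bayesian-flavoured linear-model draw: sigma^2 from scaled inv-chi-square,
# beta from N(betahat, sigma^2 (X'X)^-1), then predictive noise.
draw_lm <- function(dat, fml, obs_rows, idx) {
  f <- lm(fml, data = dat[obs_rows, ])
  X_obs <- model.matrix(f)
  df_res <- f$df.residual
  sigma2 <- sum(f$residuals^2) / stats::rchisq(1, df_res)
  XtX_inv <- chol2inv(chol(crossprod(X_obs)))
  beta <- as.numeric(coef(f) +
                       t(chol(sigma2 * XtX_inv)) %*% rnorm(length(coef(f))))
  X_new <- model.matrix(stats::delete.response(stats::terms(f)),
                        data = dat[idx, ], xlev = f$xlevels)
  as.numeric(X_new %*% beta + rnorm(length(idx), 0, sqrt(sigma2)))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' (1 + 1/m) times the between-imputation variance; the CI uses a
#' t-distribution with the Rubin degrees of freedom.
#'
#' @param estimates Numeric vector of m per-imputation point estimates.
#' @param variances Numeric vector of m per-imputation variances (>= 0).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `estimate`, `within_var`, `between_var`,
#'   `total_var`, `std.error`, `df`, `conf.low`, `conf.high`, `m`.
#' @export
#' @examples
#' rubin_pool(c(1, 3), c(1, 1)) # pooled 2, total variance 4
rubin_pool <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m == 0) {
    abort("Need at least one imputation to pool.",
          class = "kcalmsm_param_error")
  }
  if (length(variances) != m || any(variances < 0)) {
    abort("`variances` must match `estimates` and be non-negative.",
          class = "kcalmsm_param_error")
  }
  qbar <- mean(estimates)
  wbar <- mean(variances)
  if (m == 1) {
    warn("Only one imputation: between-imputation variance is undefined; total variance = within-imputation variance.")
    b <- NA_real_
    total <- wbar
    df <- Inf
  } else {
    b <- sum((estimates - qbar)^2) / (m - 1)
    total <- wbar + (1 + 1 / m) * b
    df <- if (b == 0) Inf else (m - 1) * (1 + wbar / ((1 + 1 / m) * b))^2
  }
  tq <- qt(1 - (1 - conf_level) / 2, df)
  tibble::tibble(estimate = qbar, within_var = wbar, between_var = b,
                 total_var = total, std.error = sqrt(total), df = df,
                 conf.low = qbar - tq * sqrt(total),
                 conf.high = qbar + tq * sqrt(total), m = m)
}
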