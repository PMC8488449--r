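# Weighted logistic regression for the marginal structural model, with a
# robust (sandwich) covariance, plus broom-style accessors.

#' Fit a weighted logistic regression (MSM working model)
#'
#' Maximizes the weighted Bernoulli log-likelihood by iteratively
#' reweighted least squares and reports a robust (HC0 sandwich) coefficient
#' covariance, as appropriate when observations carry estimated
#' inverse-probability weights.
#'
#' @param data Data frame containing the model variables.
#' @param formula Model formula with a binary (logical or 0/1) response.
#' @param weights Positive per-row weights; `NULL` for unweighted.
#' @param weight_source Free-text description stored on the fit.
#' @return An object of class `msm_fit`: list with `coefficients`, `vcov`
#'   (robust), `model_vcov`, `glm` (the underlying fit), `n`, `n_effective`
#'   (sum of weights), `education_coding`, `weight_source`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_children = 2000, seed = 9))
#' fit <- fit_weighted_logistic(cohort, obese_6y ~ education)
#' tidy(fit)
fit_weighted_logistic <- function(data, formula, weights = NULL,
                                  weight_source = "none") {
  y <- eval(formula[[2]], data)
  if (anyNA(y) || !all(y %in% c(0, 1, TRUE, FALSE))) {
    abort("Response must be complete and binary.", class = "kcalmsm_fit_error")
  }
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    abort("`weights` must be positive, finite, one per row.",
          class = "kcalmsm_fit_error")
  }
  dat <- data
  dat$.w <- weights
  # quasibinomial family: identical IRLS point estimates to binomial ML with
  # case weights, without spurious non-integer-count warnings
  fit <- glm(formula, family = stats::quasibinomial(), data = dat,
             weights = .w, control = list(maxit = 100, epsilon = 1e-8))
  if (!fit$converged) {
    abort(sprintf("Weighted logistic fit did not converge (deviance %.6g).",
                  fit$deviance),
          class = "kcalmsm_fit_error")
  }
  if (any(abs(coef(fit)) > 15)) {
    abort("Separation suspected: a coefficient exceeded 15 on the logit scale.",
          class = "kcalmsm_fit_error")
  }
  rvcov <- sandwich::vcovHC(fit, type = "HC0")
  edu_coding <- if ("education" %in% all.vars(formula)) "categorical"
  else if ("edu_code" %in% all.vars(formula)) "continuous_linear"
  else "none"
  structure(list(coefficients = coef(fit), vcov = rvcov,
                 model_vcov = vcov(fit), glm = fit,
                 formula = formula, n = nrow(dat),
                 n_effective = sum(weights),
                 education_coding = edu_coding,
                 weight_source = weight_source),
            class = "msm_fit")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Weighted logistic MSM fit\n")
  cat("  formula:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, effective n = %.1f, weights: %s\n",
              x$n, x$n_effective, x$weight_source))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @method tidy msm_fit
#' @export
tidy.msm_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - zq * out$std.error
    out$conf.high <- out$estimate + zq * out$std.error
  }
  out
}

#' @method glance msm_fit
#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_effective = x$n_effective,
                 deviance = x$glm$deviance,
                 df.residual = x$glm$df.residual,
                 converged = x$glm$converged,
                 education_coding = x$education_coding,
                 weight_source = x$weight_source)
}

# Per-child fitted probabilities from an msm_fit on (possibly modified) data.
predict_prob <- function(fit, newdata) {
  as.numeric(predict(fit$glm, newdata = newdata, type = "response"))
}
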