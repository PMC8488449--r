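# ggplot2 views of the main result types.

#' Plot an inverse-probability weight set
#'
#' Histograms of the combined weights before and after percentile
#' truncation, with the truncation bounds marked.
#'
#' @param object An `ipw_set` from [estimate_ip_weights()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipw_set
#' @export
autoplot.ipw_set <- function(object, bins = 60, ...) {
  bounds <- attr(object, "bounds")
  long <- tidyr::pivot_longer(
    object[c("combined_weight", "truncated_weight")],
    dplyr::everything(), names_to = "stage", values_to = "weight")
  long$stage <- factor(long$stage,
                       levels = c("combined_weight", "truncated_weight"),
                       labels = c("combined", "truncated"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = unname(bounds), linetype = "dashed") +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "stabilized inverse-probability weight", y = "children",
                  title = "IPW distribution and 1st/99th percentile truncation")
}

#' Plot prevalence by maternal education for a fitted model
#'
#' @param object An `msm_estimate` (unadjusted or CDE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msm_estimate
#' @export
autoplot.msm_estimate <- function(object, ...) {
  prev <- object$prevalence
  prev$group <- factor(prev$group, levels = c("overall", "low", "mid", "high"))
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$group, y = 100 * .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$conf.low,
                                        ymax = 100 * .data$conf.high),
                           width = 0.2) +
    ggplot2::labs(x = "maternal education", y = "obesity prevalence (%)",
                  title = sprintf("Predicted obesity prevalence (%s model)",
                                  object$model_tag))
}

#' Plot the pipeline model table
#'
#' Grouped bars of predicted obesity prevalence by maternal education
#' across the unadjusted, CDE and scenario models.
#'
#' @param object A `pipeline_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  mt <- object$model_table
  long <- tidyr::pivot_longer(mt[c("model_tag", "low", "mid", "high")],
                              c("low", "mid", "high"),
                              names_to = "education", values_to = "prevalence")
  long$education <- factor(long$education, levels = c("low", "mid", "high"))
  long$model_tag <- factor(long$model_tag, levels = mt$model_tag)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model_tag,
                                     y = 100 * .data$prevalence,
                                     fill = .data$education)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "obesity prevalence (%)",
                  fill = "maternal\neducation",
                  title = "Obesity prevalence by model and education group") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot pre/post intake distributions for a scenario
#'
#' @param object An `intervention_result`.
#' @param original The pre-intervention cohort the scenario was applied to.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot intervention_result
#' @export
autoplot.intervention_result <- function(object, original = NULL, bins = 60,
                                         ...) {
  post <- tibble::tibble(when = "post", intake = object$cohort$intake_kcal)
  df <- if (!is.null(original)) {
    dplyr::bind_rows(tibble::tibble(when = "pre",
                                    intake = original$intake_kcal), post)
  } else post
  df$when <- factor(df$when, levels = c("pre", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$intake, fill = .data$when)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55,
                            position = "identity") +
    ggplot2::labs(x = "daily energy intake (kcal)", y = "children",
                  fill = NULL,
                  title = sprintf("Intake under scenario '%s'", object$name))
}
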