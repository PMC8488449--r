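# End-to-end orchestration: generate (or read) -> optional missingness +
# chained imputation -> weights -> unadjusted + CDE -> scenarios -> pooled
# report bundle, all under one master seed.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] into one validated,
#' file-round-trippable object. The master seed drives all stochastic
#' stages through the counter scheme of [derive_seed()] (cohort = stage 1,
#' missingness = 2, imputation = 3, scenarios = 4, bootstrap = 5), so the
#' same configuration always yields identical outputs.
#'
#' @param n_children Cohort size (default 2001).
#' @param seed Master seed.
#' @param generator Named list of overrides passed to [cohort_params()].
#' @param cohort_file Optional path to an existing cohort file; when set,
#'   generation is skipped.
#' @param missingness `NULL`, or a list with `probs`, `mechanism`,
#'   `education_or` (see [missingness_spec()]).
#' @param m Number of imputations when `missingness` is set.
#' @param cycles Chained-equation cycles.
#' @param scenarios `"builtin"` or a list of [scenario_spec()] objects.
#' @param ci_method `"delta"` or `"bootstrap"` for the unadjusted/CDE
#'   inequality CIs.
#' @param boot_reps Bootstrap replicates (used when `ci_method =
#'   "bootstrap"`; default 199 here, sized for routine cohort runs).
#' @param include_sex Include sex in the mediator weight models.
#' @param conf_level Confidence level for all intervals.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_children = 2001, seed = 1L, generator = list(),
                            cohort_file = NULL, missingness = NULL, m = 5,
                            cycles = 10, scenarios = "builtin",
                            ci_method = c("delta", "bootstrap"),
                            boot_reps = 199, include_sex = TRUE,
                            conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  structure(list(n_children = n_children, seed = as.integer(seed),
                 generator = generator, cohort_file = cohort_file,
                 missingness = missingness, m = m, cycles = cycles,
                 scenarios = scenarios, ci_method = ci_method,
                 boot_reps = boot_reps, include_sex = include_sex,
                 conf_level = conf_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file to read or write.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
          class = "kcalmsm_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) a cohort, optionally masks and multiply imputes,
#' estimates inverse-probability weights, fits the unadjusted and
#' controlled-direct-effect models, simulates the configured intervention
#' scenarios by g-computation, and assembles a report bundle: a
#' descriptive table, a six-row model table (unadjusted, CDE, one row per
#' scenario) with consuming-at-or-below-EAR, per-education prevalence,
#' percent change versus CDE, risk-ratio and risk-difference columns,
#' weight diagnostics, and a provenance log. With multiple imputations,
#' prevalences, log risk ratios and risk differences are pooled by Rubin's
#' rules over delta-method variances.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when set the report tables and log
#'   are written there via [write_pipeline_report()].
#' @return A `pipeline_result`: list with `descriptive`, `model_table`,
#'   `weight_diagnostics`, `log`, `cohort`, `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_children = 1500, seed = 7))
#' res$model_table
#' }
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  master <- config$seed
  log_lines <- c(
    sprintf("kcalmsm %s, %s", as.character(utils::packageVersion("kcalmsm")),
            R.version.string),
    sprintf("config hash: %s", rlang::hash(unclass(config))),
    sprintf("master seed: %d", master))

  cohort <- stage("generate", {
    if (!is.null(config$cohort_file)) read_cohort(config$cohort_file)
    else {
      gp <- utils::modifyList(
        list(n_children = config$n_children, seed = derive_seed(master, 1)),
        config$generator)
      generate_cohort(do.call(cohort_params, gp))
    }
  })
  log_lines <- c(log_lines, sprintf("cohort: %d children", nrow(cohort)))

  completed <- stage("imputation", {
    if (is.null(config$missingness)) list(cohort)
    else {
      ms <- missingness_spec(config$missingness$probs,
                             config$missingness$mechanism %||% "MCAR",
                             config$missingness$education_or %||% 1.5,
                             seed = derive_seed(master, 2))
      masked <- impose_missingness(cohort, ms)
      chained_imputation(masked, m = config$m,
                         seed = derive_seed(master, 3),
                         cycles = config$cycles)$imputations
    }
  })
  m <- length(completed)
  log_lines <- c(log_lines, sprintf("analysis datasets: %d", m))

  scen_seed <- derive_seed(master, 4)
  boot_seed <- derive_seed(master, 5)
  per_imp <- stage("models", lapply(completed, function(dat) {
    fit_model_rows(dat, config, scen_seed, boot_seed)
  }))
  model_table <- stage("pooling", pool_model_rows(per_imp, config$conf_level))
  wdiag <- stage("weights", weight_diagnostics(
    estimate_ip_weights(completed[[1]], config$include_sex)))
  descriptive <- stage("descriptives", describe_cohort(completed[[1]]))
  log_lines <- c(log_lines,
                 sprintf("model rows: %d", nrow(model_table)),
                 sprintf("scenario seed: %d; bootstrap seed: %d",
                         scen_seed, boot_seed))

  res <- structure(list(descriptive = descriptive,
                        model_table = model_table,
                        weight_diagnostics = wdiag, log = log_lines,
                        cohort = cohort, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

# One completed dataset -> 6 model rows with the variances needed for
# Rubin pooling (prevalence scale; log scale for the risk ratio).
fit_model_rows <- function(dat, config, scen_seed, boot_seed) {
  zq <- qnorm(1 - (1 - config$conf_level) / 2)
  unadj <- estimate_unadjusted(dat, ci_method = config$ci_method,
                               boot_reps = config$boot_reps,
                               seed = boot_seed,
                               conf_level = config$conf_level)
  cde <- estimate_cde(dat, ci_method = config$ci_method,
                      boot_reps = config$boot_reps, seed = boot_seed,
                      conf_level = config$conf_level,
                      include_sex = config$include_sex)
  scenarios <- if (identical(config$scenarios, "builtin"))
    build_builtin_scenarios(dat, seed = scen_seed)
  else config$scenarios
  sims <- lapply(scenarios, function(sp) simulate_impact(dat, sp, cde))

  ear0 <- proportion_at_or_below_ear(dat)
  est_row <- function(est, tag, ear_b, ear_g, prev, ineq, pct_change) {
    groups <- c("overall", "low", "mid", "high")
    pe <- prev$estimate[match(groups, prev$group)]
    pv <- ((prev$conf.high - prev$conf.low) / (2 * zq))^2
    pv <- pv[match(groups, prev$group)]
    tibble::tibble(
      model_tag = tag, ear_boys = ear_b, ear_girls = ear_g,
      overall = pe[1], low = pe[2], mid = pe[3], high = pe[4],
      overall_var = pv[1], low_var = pv[2], mid_var = pv[3], high_var = pv[4],
      rr = ineq$rr, log_rr_var = ((log(ineq$rr_hi) - log(ineq$rr_lo)) / (2 * zq))^2,
      rd = ineq$rd, rd_var = ((ineq$rd_hi - ineq$rd_lo) / (2 * zq))^2
    )
  }
  rows <- list(
    est_row(unadj, "unadjusted",
            ear0$proportion[ear0$sex == "male"],
            ear0$proportion[ear0$sex == "female"],
            unadj$prevalence, unadj$inequality, NULL),
    est_row(cde, "cde",
            ear0$proportion[ear0$sex == "male"],
            ear0$proportion[ear0$sex == "female"],
            cde$prevalence, cde$inequality, NULL))
  for (sim in sims) {
    post <- sim$ear_proportions[sim$ear_proportions$when == "post", ]
    rows <- c(rows, list(est_row(sim, sim$name,
                                 post$proportion[post$sex == "male"],
                                 post$proportion[post$sex == "female"],
                                 sim$prevalence, sim$inequality, NULL)))
  }
  dplyr::bind_rows(rows)
}

pool_model_rows <- function(per_imp, conf_level) {
  m <- length(per_imp)
  groups <- c("overall", "low", "mid", "high")
  tags <- per_imp[[1]]$model_tag
  pooled <- purrr::map_dfr(seq_along(tags), function(i) {
    rows <- purrr::map_dfr(per_imp, ~ .x[i, ])
    pool1 <- function(est, var) rubin_pool(est, var, conf_level)
    prev <- lapply(groups, function(g)
      suppressWarnings(pool1(rows[[g]], rows[[paste0(g, "_var")]])))
    names(prev) <- groups
    rrp <- suppressWarnings(pool1(log(rows$rr), rows$log_rr_var))
    rdp <- suppressWarnings(pool1(rows$rd, rows$rd_var))
    tibble::tibble(
      model_tag = tags[i],
      ear_boys = mean(rows$ear_boys), ear_girls = mean(rows$ear_girls),
      overall = prev$overall$estimate,
      overall_lo = max(0, prev$overall$conf.low),
      overall_hi = min(1, prev$overall$conf.high),
      low = prev$low$estimate, mid = prev$mid$estimate,
      high = prev$high$estimate,
      rr = exp(rrp$estimate), rr_lo = exp(rrp$conf.low),
      rr_hi = exp(rrp$conf.high),
      rd = rdp$estimate, rd_lo = rdp$conf.low, rd_hi = rdp$conf.high)
  })
  cde_row <- pooled[pooled$model_tag == "cde", ]
  pct <- function(x, ref) 100 * (x - ref) / ref
  dplyr::mutate(pooled,
    overall_chg = ifelse(.data$model_tag %in% c("unadjusted", "cde"), NA_real_,
                         pct(.data$overall, cde_row$overall)),
    low_chg = ifelse(.data$model_tag %in% c("unadjusted", "cde"), NA_real_,
                     pct(.data$low, cde_row$low)),
    mid_chg = ifelse(.data$model_tag %in% c("unadjusted", "cde"), NA_real_,
                     pct(.data$mid, cde_row$mid)),
    high_chg = ifelse(.data$model_tag %in% c("unadjusted", "cde"), NA_real_,
                      pct(.data$high, cde_row$high))
  )[, c("model_tag", "ear_boys", "ear_girls", "overall", "overall_lo",
        "overall_hi", "overall_chg", "low", "low_chg", "mid", "mid_chg",
        "high", "high_chg", "rr", "rr_lo", "rr_hi", "rd", "rd_lo", "rd_hi")]
}

#' Descriptive summary of a cohort
#'
#' Counts and percentages for the categorical analysis variables plus the
#' median daily energy intake (overall and by sex), in a long tibble.
#'
#' @param cohort Cohort tibble.
#' @return A tibble with columns `variable`, `level`, `n`, `value`.
#' @export
describe_cohort <- function(cohort) {
  cat_block <- function(var) {
    x <- cohort[[var]]
    tab <- table(x, useNA = "no")
    tibble::tibble(variable = var, level = names(tab),
                   n = as.integer(tab),
                   value = 100 * as.integer(tab) / sum(tab))
  }
  cats <- purrr::map_dfr(c("sex", "education", "ethnicity",
                           "birthweight_cat", "health", "activity_cat",
                           "tv_cat", "imd_quintile"), cat_block)
  med <- tibble::tibble(
    variable = "intake_kcal",
    level = c("median_overall", "median_male", "median_female"),
    n = c(sum(!is.na(cohort$intake_kcal)),
          sum(!is.na(cohort$intake_kcal) & cohort$sex == "male"),
          sum(!is.na(cohort$intake_kcal) & cohort$sex == "female")),
    value = c(median(cohort$intake_kcal, na.rm = TRUE),
              median(cohort$intake_kcal[cohort$sex == "male"], na.rm = TRUE),
              median(cohort$intake_kcal[cohort$sex == "female"], na.rm = TRUE)))
  obesity <- purrr::map_dfr(c("bmi_z_3y", "bmi_z_6y"), function(v) {
    z <- cohort[[v]][!is.na(cohort[[v]])]
    tab <- table(classify_bmi_status(z))
    tibble::tibble(variable = v, level = names(tab), n = as.integer(tab),
                   value = 100 * as.integer(tab) / sum(tab))
  })
  dplyr::bind_rows(cats, med, obesity)
}

#' Write the pipeline report bundle
#'
#' Writes `descriptive.tsv`, `model_table.tsv` (percentages to 1 decimal
#' place, risk ratios to 2), `weight_diagnostics.tsv` and `run_log.txt`
#' into `out_dir`. Identical configurations produce byte-identical files.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  mt <- result$model_table
  out <- tibble::tibble(
    model_tag = mt$model_tag,
    ear_boys_pct = fmt1(100 * mt$ear_boys),
    ear_girls_pct = fmt1(100 * mt$ear_girls),
    overall_pct = fmt1(100 * mt$overall),
    overall_chg_pct = fmt1(mt$overall_chg),
    low_pct = fmt1(100 * mt$low), low_chg_pct = fmt1(mt$low_chg),
    mid_pct = fmt1(100 * mt$mid), mid_chg_pct = fmt1(mt$mid_chg),
    high_pct = fmt1(100 * mt$high), high_chg_pct = fmt1(mt$high_chg),
    rr = sprintf("%.2f", mt$rr),
    rr_ci = sprintf("%.2f-%.2f", mt$rr_lo, mt$rr_hi),
    rd = fmt1(mt$rd), rd_ci = sprintf("%.1f-%.1f", mt$rd_lo, mt$rd_hi))
  readr::write_tsv(out, file.path(out_dir, "model_table.tsv"))
  readr::write_tsv(result$descriptive, file.path(out_dir, "descriptive.tsv"))
  readr::write_tsv(result$weight_diagnostics,
                   file.path(out_dir, "weight_diagnostics.tsv"))
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d children, %d model rows\n",
              nrow(x$cohort), nrow(x$model_table)))
  print(x$model_table)
  invisible(x)
}
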