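# LMS growth reference: BMI z-scores, centile classification, EAR energy
# constants. Ships a synthetic (toy) LMS table; licensed national reference
# coefficients are deliberately not bundled.

#' Epidemiological BMI centile cut-offs on the z-scale
#'
#' Standard-normal quantiles of the 85th and 95th centiles: a child is
#' overweight if z > 1.0364 and obese if z > 1.6449 (strictly greater).
#' @format Numeric scalars.
#' @name bmi_cutoffs
NULL

#' @rdname bmi_cutoffs
#' @export
OVERWEIGHT_Z_CUTOFF <- qnorm(0.85)

#' @rdname bmi_cutoffs
#' @export
OBESE_Z_CUTOFF <- qnorm(0.95)

#' Synthetic LMS growth reference
#'
#' A small synthetic age- and sex-indexed (L, M, S) table spanning ages 2-8
#' years, with the characteristic early-childhood dip and rebound in median
#' BMI. It is a stand-in with the right shape for testing and simulation,
#' not a measurement-based national reference.
#'
#' @return A tibble with columns `sex`, `age_years`, `L` (Box-Cox power),
#'   `M` (median BMI, kg/m^2), `S` (coefficient of variation).
#' @export
#' @examples
#' head(lms_reference())
lms_reference <- function() {
  ages <- 2:8
  tibble::tibble(
    sex = rep(c("male", "female"), each = length(ages)),
    age_years = rep(ages, 2),
    L = c(-1.35, -1.45, -1.55, -1.65, -1.75, -1.85, -1.90,
          -1.30, -1.40, -1.50, -1.60, -1.70, -1.80, -1.85),
    M = c(16.6, 16.2, 15.9, 15.7, 15.6, 15.7, 15.9,
          16.3, 16.0, 15.7, 15.5, 15.4, 15.5, 15.8),
    S = c(0.078, 0.080, 0.083, 0.086, 0.090, 0.094, 0.098,
          0.082, 0.085, 0.088, 0.092, 0.096, 0.100, 0.104)
  )
}

#' Read an LMS reference file
#'
#' @param path Delimited text file with columns `sex`, `age_years`, `L`,
#'   `M`, `S`.
#' @return A validated LMS tibble.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(ref, c("sex", "age_years", "L", "M", "S"),
              what = sprintf("LMS file '%s'", path))
  validate_lms_reference(ref)
}

validate_lms_reference <- function(ref) {
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort("LMS reference requires M > 0 and S > 0.",
          class = "kcalmsm_param_error")
  }
  ok_order <- all(vapply(split(ref$age_years, ref$sex),
                         function(a) all(diff(a) > 0), TRUE))
  if (!ok_order) {
    abort("LMS reference ages must be strictly increasing within sex.",
          class = "kcalmsm_param_error")
  }
  ref
}

# Linear interpolation of (L, M, S) in age within sex.
lms_at <- function(age, sex, ref) {
  rows <- ref[ref$sex == as.character(sex), ]
  if (!nrow(rows) || age < min(rows$age_years) || age > max(rows$age_years)) {
    abort(sprintf("Age %.2f (%s) is outside the LMS reference range.",
                  age, sex),
          class = "kcalmsm_range_error")
  }
  if (nrow(rows) == 1L) {
    return(list(L = rows$L, M = rows$M, S = rows$S))
  }
  list(L = stats::approx(rows$age_years, rows$L, age)$y,
       M = stats::approx(rows$age_years, rows$M, age)$y,
       S = stats::approx(rows$age_years, rows$S, age)$y)
}

#' BMI z-score by the LMS method
#'
#' Computes z = ((X/M)^L - 1) / (L S) (or log(X/M)/S when L = 0) with
#' (L, M, S) linearly interpolated in age within sex.
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @param age Age in years, within the reference range.
#' @param sex `"male"` or `"female"`.
#' @param ref LMS reference tibble; defaults to the synthetic [lms_reference()].
#' @return The BMI z-score (scalar; vectorized over `bmi`, `age`, `sex`).
#' @export
#' @examples
#' lms_zscore(17.5, age = 6, sex = "male")
lms_zscore <- function(bmi, age, sex, ref = lms_reference()) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    abort("`bmi` must be positive and finite.", class = "kcalmsm_param_error")
  }
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(as.character(sex), n)
  vapply(seq_len(n), function(i) {
    g <- lms_at(age[i], sex[i], ref)
    if (abs(g$L) < 1e-12) log(bmi[i] / g$M) / g$S
    else ((bmi[i] / g$M)^g$L - 1) / (g$L * g$S)
  }, numeric(1))
}

#' @rdname lms_zscore
#' @param z BMI z-score to invert back to a BMI value.
#' @export
lms_bmi_from_z <- function(z, age, sex, ref = lms_reference()) {
  n <- max(length(z), length(age), length(sex))
  z <- rep_len(z, n); age <- rep_len(age, n); sex <- rep_len(as.character(sex), n)
  vapply(seq_len(n), function(i) {
    g <- lms_at(age[i], sex[i], ref)
    if (abs(g$L) < 1e-12) g$M * exp(g$S * z[i])
    else g$M * (1 + g$L * g$S * z[i])^(1 / g$L)
  }, numeric(1))
}

#' Classify BMI status from a z-score
#'
#' Epidemiological cut-offs: obese if z > 1.6449 (95th centile), overweight
#' if 1.0364 < z <= 1.6449 (85th centile), otherwise not overweight. Both
#' comparisons are strict, per the "greater than the centile" convention.
#'
#' @param z Finite BMI z-score(s).
#' @return A factor with levels `not_overweight`, `overweight`, `obese`.
#' @export
#' @examples
#' classify_bmi_status(c(-0.2, 1.2, 1.7))
classify_bmi_status <- function(z) {
  if (any(!is.finite(z))) {
    abort("`z` must be finite.", class = "kcalmsm_param_error")
  }
  factor(ifelse(z > OBESE_Z_CUTOFF, "obese",
                ifelse(z > OVERWEIGHT_Z_CUTOFF, "overweight", "not_overweight")),
         levels = c("not_overweight", "overweight", "obese"))
}

#' Estimated average requirement (EAR) energy constants
#'
#' Reference daily energy needs by sex and age. The default table carries
#' the age-3 constants used throughout the intervention scenarios: 1171.0
#' kcal/day for boys and 1076.0 kcal/day for girls.
#'
#' @return A tibble with columns `sex`, `age_years`, `kcal`.
#' @export
ear_reference <- function() {
  tibble::tibble(sex = c("male", "female"), age_years = c(3, 3),
                 kcal = c(1171.0, 1076.0))
}

#' @rdname ear_reference
#' @param path Delimited text file with columns `sex`, `age_years`, `kcal`.
#' @export
read_ear_reference <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(tab, c("sex", "age_years", "kcal"),
              what = sprintf("EAR file '%s'", path))
  if (any(tab$kcal <= 0)) {
    abort("EAR values must be positive.", class = "kcalmsm_param_error")
  }
  tab
}

#' Look up an EAR constant
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age Age in years.
#' @param table EAR table; defaults to [ear_reference()].
#' @return kcal/day value(s).
#' @export
#' @examples
#' ear_lookup("male", 3)
ear_lookup <- function(sex, age = 3, table = ear_reference()) {
  n <- max(length(sex), length(age))
  sex <- rep_len(as.character(sex), n); age <- rep_len(age, n)
  vapply(seq_len(n), function(i) {
    hit <- table$sex == sex[i] & table$age_years == age[i]
    if (!any(hit)) {
      abort(sprintf("No EAR tabulated for (%s, age %s).", sex[i], age[i]),
            class = "kcalmsm_lookup_error")
    }
    table$kcal[which(hit)[1]]
  }, numeric(1))
}
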