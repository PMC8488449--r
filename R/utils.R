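# Internal helpers shared across modules.

EDU_LEVELS <- c("low", "mid", "high")
SEX_LEVELS <- c("male", "female")
ETH_LEVELS <- c("white", "non_white")
CAT3_LEVELS <- c("low", "mid", "high")
HEALTH_LEVELS <- c("good", "fair_bad")

# Disadvantage coding used throughout: high = 0, mid = 1, low = 2, so a
# positive coefficient means excess risk with lower maternal education.
edu_code <- function(education) {
  unname(c(low = 2, mid = 1, high = 0)[as.character(education)])
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Deterministic counter scheme: each pipeline stage draws from its own
#' stream, so adding a stage never perturbs the streams of earlier stages.
#' The result stays below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Small non-negative integer stage counter.
#' @return An integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stage), length(stage) == 1L, stage >= 0)
  as.integer((abs(as.integer(master)) %% 1048573L) * 1024L + as.integer(stage) %% 1024L)
}

assert_prob <- function(x, name, open_upper = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(if (open_upper) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be probability values in [0,%s].", name,
                  if (open_upper) "1)" else "1]"),
          class = "kcalmsm_param_error")
  }
  invisible(x)
}

assert_cols <- function(data, cols, what = "cohort") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing_cols, collapse = ", ")),
          class = "kcalmsm_schema_error")
  }
  invisible(data)
}

# Draw from a standard normal truncated above (side = "upper") or below
# (side = "lower") a cut point, by inverse-CDF. Used to make continuous
# z-scores consistent with already-drawn binary status flags.
rtruncnorm_std <- function(n, cut, side = c("upper", "lower")) {
  side <- match.arg(side)
  u <- runif(n)
  p_cut <- pnorm(cut)
  if (side == "upper") qnorm(p_cut + u * (1 - p_cut)) else qnorm(u * p_cut)
}

# Multinomial draw per row from an n x k matrix of probabilities.
draw_categorical <- function(prob_matrix, labels) {
  stopifnot(ncol(prob_matrix) == length(labels))
  cum <- t(apply(prob_matrix, 1, cumsum))
  u <- runif(nrow(prob_matrix)) * cum[, ncol(cum)]
  idx <- rowSums(u > cum) + 1L
  factor(labels[idx], levels = labels)
}

# Softmax over per-row logit columns.
softmax_rows <- function(logits) {
  m <- exp(logits - apply(logits, 1, max))
  m / rowSums(m)
}
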