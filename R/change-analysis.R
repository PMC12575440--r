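# Pre/post change scores, effect sizes, the baseline-adjusted between-block
# contrast, and covariate-adjusted regressions.

# Outcomes whose between-block effect size is computed on %-point changes
# (already-percent outcomes) rather than percent changes.
PCT_POINT_OUTCOMES <- c("frac_util_4mmol_pct", "frac_util_15min_pct",
                        "ge_fresh_3rd_pct", "ge_fresh_2nd_pct",
                        "ge_tired_3rd_pct", "ge_tired_2nd_pct")

#' Pre/post change scores
#'
#' Joins pre and post outcome tables on participant x block x outcome and
#' computes per-participant absolute changes (`delta = post - pre`) and
#' percent changes (`pct = 100 * delta / pre`). Unmatched keys are reported
#' and excluded.
#'
#' @param pre,post Long-format data frames with columns `participant_id`,
#'   `block`, `outcome`, `value`. A wide battery table can be converted with
#'   [battery_long()].
#' @return A tibble of class `change_scores` with one row per participant x
#'   block x outcome: `pre`, `post`, `delta`, `pct`. The number of excluded
#'   unmatched rows is attached as attribute `n_unmatched`.
#' @export
change_scores <- function(pre, post) {
  keys <- c("participant_id", "block", "outcome")
  stopifnot(all(c(keys, "value") %in% names(pre)),
            all(c(keys, "value") %in% names(post)))
  joined <- dplyr::inner_join(
    dplyr::rename(pre, pre = "value"),
    dplyr::rename(post, post = "value"),
    by = keys
  )
  n_unmatched <- (nrow(pre) - nrow(joined)) + (nrow(post) - nrow(joined))
  if (n_unmatched > 0) {
    rlang::warn(sprintf("%d unmatched pre/post rows excluded", n_unmatched))
  }
  out <- dplyr::mutate(joined,
    delta = .data$post - .data$pre,
    pct = ifelse(.data$pre != 0, 100 * .data$delta / .data$pre, NA_real_)
  )
  structure(out, n_unmatched = n_unmatched,
            class = c("change_scores", class(out)))
}

#' Convert a wide battery table to long outcome format
#'
#' @param batteries A battery-result table (one row per participant x block x
#'   timepoint) as produced by [assemble_battery()] or [analyze_dataset()].
#' @param outcomes Columns to keep as outcomes; defaults to every numeric
#'   outcome column except body mass.
#' @return Long tibble with `participant_id`, `block`, `timepoint`, `outcome`,
#'   `value`.
#' @export
battery_long <- function(batteries, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(batteries)[vapply(batteries, is.numeric, logical(1))],
                        "body_mass_kg")
  }
  tidyr::pivot_longer(
    batteries[c("participant_id", "block", "timepoint", outcomes)],
    cols = dplyr::all_of(outcomes),
    names_to = "outcome", values_to = "value"
  )
}

#' Cohen's d between two sets of change scores
#'
#' The two-sample pooled-SD form: `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`.
#' Inputs are percent changes, or %-point changes for outcomes that are
#' themselves percentages (gross efficiency, fractional utilization).
#'
#' @param a,b Numeric vectors of (percent) changes, each of length >= 2.
#' @return Cohen's d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    rlang::abort("zero pooled SD: effect size undefined",
                 class = "blocktrain_invalid_argument")
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Paired (within-subject) standardized effect: mean difference / SD of the
# paired differences. Reported alongside the pooled d for reference; the
# interpretation scale below applies to the pooled form.
cohens_dz <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    rlang::abort("zero SD of differences: effect size undefined",
                 class = "blocktrain_invalid_argument")
  }
  mean(d) / stats::sd(d)
}

#' Effect-size magnitude label (highly trained scale)
#'
#' Interprets |d| on the scale for highly trained subjects: 0.0-0.24 trivial,
#' 0.25-0.49 small, 0.5-1.0 moderate, > 1.0 large.
#'
#' @param d Cohen's d (vectorized).
#' @return Character label.
#' @examples
#' rhea_label(c(0, -0.34, 0.64, 1.2))
#' @export
rhea_label <- function(d) {
  ad <- abs(d)
  dplyr::case_when(
    ad < 0.25 ~ "trivial",
    ad < 0.5 ~ "small",
    ad <= 1.0 ~ "moderate",
    TRUE ~ "large"
  )
}

#' Between-block comparison of one outcome
#'
#' Within-block change statistics and the baseline-adjusted between-block
#' contrast for a two-period within-subject design with complete pairs. The
#' contrast regresses the per-participant difference of changes (block A minus
#' block B) on the difference of baselines; its intercept estimates the
#' block-by-time effect at equal baselines. For complete balanced two-period
#' data this equals the block-by-time contrast of a mixed model with the
#' baseline as covariate and a participant random intercept. Within-block
#' p-values are paired t-tests on the deltas (labelled as such in the output).
#'
#' @param changes A [change_scores()] table (or compatible data frame).
#' @param outcome Outcome name to compare.
#' @param blocks Length-2 character: the two block labels, contrast is
#'   `blocks[1] - blocks[2]`.
#' @param pct_points Use %-point changes (deltas) rather than percent changes
#'   for the effect size; defaults by outcome metadata (percent-type outcomes
#'   such as gross efficiency use %-points).
#' @return A one-row tibble: per-block mean/SD of delta and pct, within-block
#'   paired p, baseline-adjusted contrast with 95% CI and p, Cohen's d (pooled
#'   and paired forms) with magnitude label. Incomplete pairs are excluded;
#'   their count is in `n_excluded`.
#' @export
compare_blocks <- function(changes, outcome, blocks = c("MIT", "HIT"),
                           pct_points = outcome %in% PCT_POINT_OUTCOMES) {
  stopifnot(length(blocks) == 2L)
  x <- changes[changes$outcome == outcome & changes$block %in% blocks, , drop = FALSE]
  if (nrow(x) == 0L) {
    rlang::abort(sprintf("outcome '%s' not present", outcome),
                 class = "blocktrain_invalid_argument")
  }
  wide <- tidyr::pivot_wider(
    x[c("participant_id", "block", "pre", "delta", "pct")],
    names_from = "block", values_from = c("pre", "delta", "pct")
  )
  need <- paste(rep(c("pre", "delta", "pct"), each = 2), rep(blocks, 3), sep = "_")
  complete <- stats::complete.cases(wide[need])
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    rlang::warn(sprintf("%d incomplete pairs excluded for '%s'", n_excluded, outcome))
  }
  w <- wide[complete, , drop = FALSE]
  if (nrow(w) < 3L) {
    rlang::abort("need >= 3 complete pairs for the adjusted contrast",
                 class = "blocktrain_invalid_argument")
  }
  dA <- w[[paste0("delta_", blocks[1])]]; dB <- w[[paste0("delta_", blocks[2])]]
  bA <- w[[paste0("pre_", blocks[1])]];   bB <- w[[paste0("pre_", blocks[2])]]
  pA <- w[[paste0("pct_", blocks[1])]];   pB <- w[[paste0("pct_", blocks[2])]]

  # baseline-adjusted within-subject contrast: difference of deltas on
  # difference of baselines (centered so the intercept is the contrast at
  # equal baselines)
  diffs <- dA - dB
  near_const <- function(x) stats::sd(x) <= 1e-10 * (mean(abs(x)) + 1)
  if (near_const(diffs)) {  # degenerate: identical change in both blocks
    contrast <- mean(diffs)
    contrast_lo <- contrast_hi <- contrast
    p_bt <- if (abs(contrast) <= 1e-10) 1 else 0
  } else {
    fit <- stats::lm(diffs ~ I(bA - bB - mean(bA - bB)))
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)[1, ]
    contrast <- sm[1, "Estimate"]
    contrast_lo <- ci[1]; contrast_hi <- ci[2]
    p_bt <- sm[1, "Pr(>|t|)"]
  }

  esA <- if (pct_points) dA else pA
  esB <- if (pct_points) dB else pB
  same_mean <- abs(mean(esA) - mean(esB)) <= 1e-10
  d <- if (near_const(esA) && near_const(esB) && same_mean) 0
       else cohens_d(esA, esB)
  dz <- if (near_const(esA - esB) && same_mean) 0 else cohens_dz(esA, esB)
  # paired t on deltas; constant zero deltas mean "no change" (p = 1)
  safe_p <- function(x) {
    if (near_const(x)) return(if (abs(mean(x)) <= 1e-10) 1 else 0)
    stats::t.test(x)$p.value
  }

  tibble::tibble(
    outcome = outcome, n = nrow(w),
    n_excluded = n_excluded,
    mean_delta_a = mean(dA), sd_delta_a = stats::sd(dA),
    mean_delta_b = mean(dB), sd_delta_b = stats::sd(dB),
    mean_pct_a = mean(pA), sd_pct_a = stats::sd(pA),
    mean_pct_b = mean(pB), sd_pct_b = stats::sd(pB),
    p_within_a = safe_p(dA),
    p_within_b = safe_p(dB),
    contrast = contrast,
    contrast_lo = contrast_lo, contrast_hi = contrast_hi,
    p_block_time = p_bt,
    cohens_d = d,
    cohens_dz = dz,
    es_scale = if (pct_points) "pct_points" else "pct_change",
    es_label = rhea_label(d)
  )
}

#' Covariate-adjusted linear regression of a change score
#'
#' Ordinary least squares of a change score on a training predictor,
#' controlling for the baseline value, the change in body mass, and optionally
#' sex. Reports the predictor's estimate (the theoretical change in the
#' outcome per unit of the predictor), its t-based 95% confidence interval and
#' p-value, and the adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param data A data frame containing all referenced columns.
#' @param response Name of the change-score column.
#' @param predictor Name of the training-variable column.
#' @param covariates Character vector of covariate column names (default
#'   baseline + body-mass change; add `"sex"` to match a sex-controlled fit).
#' @return A one-row tibble: `estimate`, `ci_lo`, `ci_hi`, `p`, `r2`,
#'   `r2_adj`, `n`.
#' @export
fit_adjusted_regression <- function(data, response, predictor,
                                    covariates = c("baseline", "d_body_mass")) {
  vars <- c(response, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
                 class = "blocktrain_invalid_argument")
  }
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  p_terms <- length(c(predictor, covariates))
  if (nrow(df) <= p_terms + 1L) {
    rlang::abort("too few observations for the requested model",
                 class = "blocktrain_invalid_argument")
  }
  form <- stats::reformulate(c(predictor, covariates), response = response)
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    rlang::abort(paste("rank-deficient design; collinear terms:",
                       paste(dropped, collapse = ", ")),
                 class = "blocktrain_invalid_argument")
  }
  sm <- summary(fit)
  ci <- stats::confint(fit)[predictor, ]
  tibble::tibble(
    response = response, predictor = predictor,
    estimate = stats::coef(fit)[[predictor]],
    ci_lo = ci[[1]], ci_hi = ci[[2]],
    p = sm$coefficients[predictor, "Pr(>|t|)"],
    r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
    n = nrow(df)
  )
}
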