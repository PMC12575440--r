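# Per-timepoint test-battery outcomes and the composite endurance performance
# index. The battery follows the prolonged-test order: lactate profile ->
# 10-s sprint -> incremental VO2max test -> 30-min bout at the 2 mmol/L power
# with repeated steps (semi-fatigued efficiency) -> 15-min maximal trial.

INDEX_INDICATORS <- c("po_vo2max_w_kg", "po_4mmol_w_kg", "po_15min_w_kg")

#' Mean power of the 15-min maximal trial
#'
#' @param power_w Uniformly sampled power trace of the trial (W).
#' @param sample_period Seconds per sample.
#' @param body_mass Body mass (kg).
#' @return Mean trial power relative to body mass (W·kg^-1).
#' @export
po_15min <- function(power_w, sample_period, body_mass) {
  stopifnot(body_mass > 0)
  dur <- length(power_w) * sample_period
  if (dur < 0.95 * 900) {
    rlang::abort(sprintf("trial lasted %.0f s; a valid 15-min trial requires >= 855 s", dur),
                 class = "blocktrain_invalid_trial")
  }
  mean(power_w) / body_mass
}

#' Best 10-s sprint power
#'
#' Maximum 10-second rolling mean of the sprint power trace.
#'
#' @param power_w Sprint power trace (W).
#' @param sample_period Seconds per sample (must divide 10 s into >= 1 sample).
#' @param body_mass Body mass (kg).
#' @return Best 10-s mean power (W·kg^-1).
#' @export
po_10sec <- function(power_w, sample_period, body_mass) {
  stopifnot(body_mass > 0)
  if (length(power_w) * sample_period < 10) {
    rlang::abort("sprint trace shorter than 10 s", class = "blocktrain_insufficient_data")
  }
  best_rolling_mean(power_w, 10, sample_period) / body_mass
}

#' Fractional utilization of VO2max during the 15-min trial
#'
#' @param series A [gas_series()] of the trial (VO2 over the whole trial).
#' @param vo2max VO2max (mL·min^-1), same units as the series VO2.
#' @return Mean trial VO2 as a percent of VO2max.
#' @export
frac_util_15min <- function(series, vo2max) {
  stopifnot(vo2max > 0)
  if (nrow(series) == 0L) {
    rlang::abort("empty series", class = "blocktrain_invalid_argument")
  }
  100 * mean(series$vo2_ml_min) / vo2max
}

#' Normalization basis for the endurance performance index
#'
#' For each of the three main performance indicators (power at VO2max, power
#' at 4 mmol·L^-1, 15-min trial power, all in W·kg^-1), records the maximum
#' value observed across the reference set of battery results. By default the
#' reference set is all observations entering the analysis (both blocks, both
#' timepoints); pass a subset to use an alternative reference.
#'
#' @param batteries A data frame of battery results containing the indicator
#'   columns `po_vo2max_w_kg`, `po_4mmol_w_kg`, `po_15min_w_kg`.
#' @return Named numeric vector of per-indicator maxima.
#' @export
index_basis <- function(batteries) {
  missing_cols <- setdiff(INDEX_INDICATORS, names(batteries))
  if (length(missing_cols)) {
    rlang::abort(paste("missing indicator columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "blocktrain_invalid_argument")
  }
  maxima <- vapply(batteries[INDEX_INDICATORS], max, numeric(1), na.rm = TRUE)
  if (any(!is.finite(maxima)) || any(maxima <= 0)) {
    rlang::abort("indicator maxima must be positive and finite",
                 class = "blocktrain_invalid_argument")
  }
  maxima
}

#' Composite endurance performance index
#'
#' The average of the three main performance indicators after normalization by
#' the maximum observed value for each indicator: `mean(x_i / max(x))`. The
#' index lies in (0, 1]; a rider holding every maximum scores exactly 1. It is
#' invariant to per-indicator rescaling (units cancel).
#'
#' @param battery A one-or-more-row data frame with the indicator columns (see
#'   [index_basis()]).
#' @param basis Per-indicator maxima from [index_basis()] over the declared
#'   reference set.
#' @return Numeric index value(s) in (0, 1].
#' @export
endurance_index <- function(battery, basis) {
  stopifnot(all(INDEX_INDICATORS %in% names(battery)),
            all(INDEX_INDICATORS %in% names(basis)))
  vals <- as.matrix(battery[INDEX_INDICATORS])
  if (anyNA(vals)) {
    rlang::abort("all three indicators are required; no partial index",
                 class = "blocktrain_invalid_argument")
  }
  as.numeric(vals %*% (1 / basis[INDEX_INDICATORS])) / length(INDEX_INDICATORS)
}

#' Assemble a battery result from raw test data
#'
#' Runs the full per-timepoint measurement chain on the raw records of one
#' prolonged test: threshold interpolation on the lactate profile, rolling-mean
#' VO2max and last-minute power on the incremental test, sprint and 15-min
#' trial powers, fractional utilizations, and gross efficiency at the third-
#' and second-last profile steps in the fresh and semi-fatigued state.
#'
#' @param profile A [lactate_profile()] (fresh state).
#' @param sprint A [gas_series()] (power only is enough) of the 10-s sprint.
#' @param vo2max_test A [gas_series()] of the incremental test (5-s sampling).
#' @param repeated_steps A [lactate_profile()]-shaped record of the third- and
#'   second-last steps repeated in the semi-fatigued state (two rows, same
#'   powers as the corresponding fresh steps), or `NULL` to skip tired GE.
#' @param trial A [gas_series()] of the 15-min maximal trial.
#' @param body_mass Body mass (kg).
#' @param participant_id,block,timepoint Identifiers carried into the result.
#' @return A one-row tibble (battery result) with outcomes in the units of the
#'   physiological-response table: powers in W·kg^-1, VO2max in
#'   mL·min^-1·kg^-1, utilizations and efficiencies in percent.
#' @export
assemble_battery <- function(profile, sprint, vo2max_test, repeated_steps,
                             trial, body_mass,
                             participant_id = NA_character_,
                             block = NA_character_, timepoint = NA_character_) {
  stopifnot(body_mass > 0)
  vo2max <- vo2max_from_series(vo2max_test)
  po_vmax <- po_vo2max(vo2max_test$power_w, sample_period(vo2max_test))
  p4 <- po_at_lactate(profile, 4)

  ge_step <- function(steps, idx_from_end) {
    i <- nrow(steps) - idx_from_end + 1L
    if (i < 1L) return(NA_real_)
    pi_j_s <- metabolic_power(steps$vo2_ml_min[i] / 60000, steps$rer[i])
    gross_efficiency(steps$power_w[i], pi_j_s)
  }
  # fresh GE from the profile's own steady-state measurements; tired GE from
  # the repeated steps after the 30-min bout
  ge_fresh_3rd <- ge_step(profile, 3L)
  ge_fresh_2nd <- ge_step(profile, 2L)
  ge_tired_3rd <- if (!is.null(repeated_steps)) ge_step(repeated_steps, 2L) else NA_real_
  ge_tired_2nd <- if (!is.null(repeated_steps)) ge_step(repeated_steps, 1L) else NA_real_

  tibble::tibble(
    participant_id = participant_id, block = block, timepoint = timepoint,
    body_mass_kg = body_mass,
    po_4mmol_w_kg = p4 / body_mass,
    po_vo2max_w_kg = po_vmax / body_mass,
    po_15min_w_kg = po_15min(trial$power_w, sample_period(trial), body_mass),
    po_10sec_w_kg = po_10sec(sprint$power_w, sample_period(sprint), body_mass),
    vo2max_ml_min_kg = vo2max / body_mass,
    frac_util_4mmol_pct = fractional_utilization_at_power(profile, vo2max, p4),
    frac_util_15min_pct = frac_util_15min(trial, vo2max),
    ge_fresh_3rd_pct = ge_fresh_3rd,
    ge_fresh_2nd_pct = ge_fresh_2nd,
    ge_tired_3rd_pct = ge_tired_3rd,
    ge_tired_2nd_pct = ge_tired_2nd
  )
}
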