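# Incremental blood-lactate profile: step protocol rules and piecewise-linear
# threshold interpolation.

#' Step-test protocol specification
#'
#' The incremental lactate-profile protocol: 5.5-min bouts starting at 125 W
#' (175 W for riders self-estimating a lactate threshold above 325 W),
#' increasing by 50 W per bout until a blood lactate of >= 2 mmol·L^-1 is
#' reached, then by 25 W per bout until >= 4 mmol·L^-1 terminates the test.
#' The start-power branch is caller-supplied via `high_start`; it is never
#' inferred from data.
#'
#' @param start_power Start power (W); overrides the `high_start` rule if given.
#' @param high_start Logical: self-estimated lactate threshold > 325 W?
#' @param coarse_increment,fine_increment Power increments (W) before/after the
#'   2 mmol·L^-1 trigger.
#' @param step_duration Bout duration (s).
#' @param fine_trigger_lactate Lactate (mmol·L^-1) switching to fine increments.
#' @param termination_lactate Lactate (mmol·L^-1) terminating the test.
#' @return A list of class `step_protocol`.
#' @export
step_protocol <- function(start_power = NULL, high_start = FALSE,
                          coarse_increment = 50, fine_increment = 25,
                          step_duration = 330, fine_trigger_lactate = 2,
                          termination_lactate = 4) {
  if (is.null(start_power)) start_power <- if (high_start) 175 else 125
  stopifnot(coarse_increment > 0, fine_increment > 0, step_duration > 0,
            fine_trigger_lactate < termination_lactate)
  structure(list(start_power = start_power,
                 coarse_increment = coarse_increment,
                 fine_increment = fine_increment,
                 step_duration = step_duration,
                 fine_trigger_lactate = fine_trigger_lactate,
                 termination_lactate = termination_lactate),
            class = "step_protocol")
}

#' Construct a lactate profile
#'
#' An ordered record of completed steps from the incremental protocol. Each
#' step carries the bout power, the end-of-bout capillary blood lactate
#' (sampled 30 s before the end), and the steady-state gas exchange (VO2, RER,
#' minutes 2.5-5.0 of the bout) plus heart rate.
#'
#' @param power_w Strictly increasing bout powers (W).
#' @param lactate_mmol_l End-step blood lactate (mmol·L^-1).
#' @param vo2_ml_min Steady-state oxygen uptake per step (mL·min^-1).
#' @param rer Steady-state RER per step.
#' @param hr_bpm Heart rate per step (bpm).
#' @param participant_id Optional identifier.
#' @param terminated Logical: did the protocol reach its termination lactate?
#'   Defaults to whether any step lactate is >= 4 mmol·L^-1.
#' @return A tibble of class `lactate_profile` with one row per step.
#' @export
lactate_profile <- function(power_w, lactate_mmol_l, vo2_ml_min = NA_real_,
                            rer = NA_real_, hr_bpm = NA_real_,
                            participant_id = NA_character_, terminated = NULL) {
  stopifnot(length(power_w) == length(lactate_mmol_l))
  if (any(diff(power_w) <= 0)) {
    rlang::abort("step powers must be strictly increasing",
                 class = "blocktrain_invalid_state")
  }
  if (any(lactate_mmol_l < 0)) {
    rlang::abort("lactate must be non-negative", class = "blocktrain_invalid_argument")
  }
  n <- length(power_w)
  if (is.null(terminated)) terminated <- any(lactate_mmol_l >= 4)
  out <- tibble::tibble(
    step_index = seq_len(n),
    power_w = as.numeric(power_w),
    lactate_mmol_l = as.numeric(lactate_mmol_l),
    vo2_ml_min = rep_len(as.numeric(vo2_ml_min), n),
    rer = rep_len(as.numeric(rer), n),
    hr_bpm = rep_len(as.numeric(hr_bpm), n)
  )
  structure(out, participant_id = participant_id, terminated = terminated,
            class = c("lactate_profile", class(out)))
}

#' @export
print.lactate_profile <- function(x, ...) {
  cat(sprintf("<lactate_profile: %d steps, %s>\n", nrow(x),
              if (isTRUE(attr(x, "terminated"))) "terminated (>= 4 mmol/L)"
              else "non-terminating"))
  NextMethod()
}

#' Next bout power under the step protocol
#'
#' Given the profile so far, returns the power of the next 5.5-min bout, or
#' `NA` once the termination lactate has been reached (test over). Coarse
#' 50 W increments apply while every lactate reading is below the 2 mmol·L^-1
#' trigger; once any reading reaches it, increments drop to 25 W.
#'
#' @param profile A [lactate_profile()] (may have zero rows).
#' @param spec A [step_protocol()].
#' @return Next power (W), or `NA_real_` for STOP.
#' @export
next_step_power <- function(profile, spec = step_protocol()) {
  if (nrow(profile) == 0L) return(spec$start_power)
  la <- profile$lactate_mmol_l
  if (any(la >= spec$termination_lactate)) return(NA_real_)
  last_p <- profile$power_w[nrow(profile)]
  inc <- if (any(la >= spec$fine_trigger_lactate)) spec$fine_increment
         else spec$coarse_increment
  last_p + inc
}

# Find the bracketing pair (i, i+1) with y[i] < level <= y[i+1] over a
# monotone-ordered x, returning the interpolated x. Exact hits return the
# (lowest) matching x directly; flat segments at the level resolve to the
# lowest bracketing x (conservative threshold).
interp_at_level <- function(x, y, level, what = "level") {
  exact <- which(y == level)
  if (length(exact) > 0L) return(x[exact[1L]])
  above <- which(y >= level)
  if (length(above) == 0L || above[1L] == 1L) {
    rlang::abort(sprintf("%s = %g not bracketed by observations (no extrapolation)",
                         what, level),
                 class = "blocktrain_not_bracketed")
  }
  hi <- above[1L]
  lo <- hi - 1L
  x[lo] + (level - y[lo]) * (x[hi] - x[lo]) / (y[hi] - y[lo])
}

#' Power output at a blood-lactate level
#'
#' Interpolates the power corresponding to a given blood lactate (typically 4
#' mmol·L^-1 for the threshold, 2 mmol·L^-1 for the prolonged-bout intensity)
#' by linear interpolation between the two bracketing steps. No extrapolation:
#' the level must lie within the observed lactate range, with at least one step
#' strictly below and one at or above it.
#'
#' @param profile A [lactate_profile()].
#' @param level Blood lactate (mmol·L^-1), default 4.
#' @return Power (W).
#' @examples
#' prof <- lactate_profile(c(175, 225, 250), c(1.4, 3.0, 4.6))
#' po_at_lactate(prof, 4)   # 240.625
#' @export
po_at_lactate <- function(profile, level = 4) {
  if (nrow(profile) < 2L && !any(profile$lactate_mmol_l == level)) {
    rlang::abort("need at least two steps to bracket a lactate level",
                 class = "blocktrain_not_bracketed")
  }
  interp_at_level(profile$power_w, profile$lactate_mmol_l, level,
                  what = "lactate")
}

#' Fractional utilization of VO2max at a power output
#'
#' Expresses the interpolated steady-state oxygen uptake at a query power as a
#' percentage of VO2max, by linear interpolation of per-step %VO2max against
#' step power. The query power must lie within the range of step powers.
#'
#' @param profile A [lactate_profile()] with `vo2_ml_min` present.
#' @param vo2max VO2max (mL·min^-1), same units as the profile's `vo2_ml_min`.
#' @param power_w Query power (W), e.g. the interpolated 4 mmol·L^-1 power.
#' @return Percent of VO2max.
#' @export
fractional_utilization_at_power <- function(profile, vo2max, power_w) {
  stopifnot(vo2max > 0)
  if (anyNA(profile$vo2_ml_min)) {
    rlang::abort("profile has missing VO2", class = "blocktrain_invalid_argument")
  }
  if (power_w < min(profile$power_w) || power_w > max(profile$power_w)) {
    rlang::abort("query power outside step range (no extrapolation)",
                 class = "blocktrain_not_bracketed")
  }
  pct <- 100 * profile$vo2_ml_min / vo2max
  stats::approx(profile$power_w, pct, xout = power_w, ties = "ordered")$y
}
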