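# Gas-exchange energetics: metabolic power input, gross efficiency, VO2max,
# and time-at-or-above computations on uniformly sampled series.

# Energetic equivalent of oxygen (J per litre O2) as a linear function of RER,
# clamped at RER = 1.0 because the equivalent is undefined for net anaerobic
# exchange (RER > 1 reflects non-steady-state CO2 washout, not substrate mix).
O2_EQ_SLOPE  <- 4840  # J·L^-1 per unit RER
O2_EQ_OFFSET <- 16890 # J·L^-1

#' Construct a gas-exchange series
#'
#' A `gas_series` is a tibble of uniformly sampled measurements from a cycling
#' test or training session: power, heart rate, oxygen uptake and respiratory
#' exchange ratio, with a segment label distinguishing warm-up, work intervals
#' and recovery. The sampling period (seconds between samples) is carried as an
#' attribute so all time-based computations are defined in seconds, not samples.
#'
#' @param t_s Sample times in seconds from session start.
#' @param power_w Mechanical power output (W).
#' @param vo2_ml_min Oxygen uptake (mL·min^-1), absolute. May be `NA` for
#'   power-only sessions.
#' @param rer Respiratory exchange ratio (dimensionless). May be `NA`.
#' @param hr_bpm Heart rate (beats·min^-1). May be `NA`.
#' @param segment Character segment labels, e.g. `"warmup"`, `"work_1"`,
#'   `"recovery_1"`. Work intervals must match `"^work"` to be picked up by
#'   work-interval summaries.
#' @param sample_period Seconds between consecutive samples (5 for laboratory
#'   tests, 10 for training sessions).
#'
#' @return A tibble of class `gas_series` with a `sample_period` attribute.
#' @export
gas_series <- function(t_s, power_w, vo2_ml_min = NA_real_, rer = NA_real_,
                       hr_bpm = NA_real_, segment = "work_1", sample_period = 10) {
  stopifnot(is.numeric(t_s), is.numeric(power_w), length(sample_period) == 1L,
            sample_period > 0)
  n <- length(t_s)
  out <- tibble::tibble(
    t_s = as.numeric(t_s),
    power_w = rep_len(as.numeric(power_w), n),
    vo2_ml_min = rep_len(as.numeric(vo2_ml_min), n),
    rer = rep_len(as.numeric(rer), n),
    hr_bpm = rep_len(as.numeric(hr_bpm), n),
    segment = rep_len(as.character(segment), n)
  )
  if (any(out$vo2_ml_min < 0, na.rm = TRUE)) {
    rlang::abort("vo2_ml_min must be non-negative", class = "blocktrain_invalid_argument")
  }
  structure(out, sample_period = sample_period,
            class = c("gas_series", class(out)))
}

#' @rdname gas_series
#' @param x A `gas_series`.
#' @export
sample_period <- function(x) {
  p <- attr(x, "sample_period", exact = TRUE)
  if (is.null(p)) rlang::abort("not a gas_series: missing sample_period")
  p
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("<gas_series: %d samples @ %gs, %.1f min, %d segments>\n",
              nrow(x), sample_period(x),
              nrow(x) * sample_period(x) / 60,
              length(unique(x$segment))))
  NextMethod()
}

is_work_segment <- function(segment) grepl("^work", segment)

#' Metabolic power input from oxygen uptake and RER
#'
#' Converts an oxygen uptake (L·s^-1) and respiratory exchange ratio into
#' metabolic power input (J·s^-1) using the linear energetic equivalent of
#' oxygen: `PI = vo2 * (4840 * RER + 16890)` with RER clamped at 1.0 (the
#' substrate-mix equivalent is undefined above 1; values above 1 indicate
#' non-steady-state measurement and are treated as pure carbohydrate).
#'
#' @param vo2_l_s Oxygen uptake in litres per second (note the unit; divide
#'   mL·min^-1 by 60000).
#' @param rer Respiratory exchange ratio, must lie in \[0.6, 1.3\].
#' @return Metabolic power input in J·s^-1 (W), vectorized.
#' @examples
#' metabolic_power(1, 1)            # 21730
#' metabolic_power(4 / 60, 0.90)    # a 4 L/min effort at RER 0.90
#' @export
metabolic_power <- function(vo2_l_s, rer) {
  if (any(vo2_l_s < 0, na.rm = TRUE)) {
    rlang::abort("vo2 must be non-negative", class = "blocktrain_invalid_argument")
  }
  if (any(rer < 0.6 | rer > 1.3, na.rm = TRUE)) {
    rlang::abort("rer outside physiological range [0.6, 1.3]",
                 class = "blocktrain_invalid_argument")
  }
  rer_eff <- pmin(rer, 1.0)
  vo2_l_s * (O2_EQ_SLOPE * rer_eff + O2_EQ_OFFSET)
}

#' Gross efficiency
#'
#' The ratio of mechanical power output to metabolic power input, as a
#' percentage: `GE = 100 * PO / PI`. Well-trained cyclists sit near 19-20%.
#'
#' @param power_w Mechanical power output (W).
#' @param pi_j_s Metabolic power input (J·s^-1), e.g. from [metabolic_power()].
#' @return Gross efficiency (%), vectorized.
#' @export
gross_efficiency <- function(power_w, pi_j_s) {
  if (any(pi_j_s <= 0, na.rm = TRUE)) {
    rlang::abort("metabolic power input must be positive",
                 class = "blocktrain_invalid_argument")
  }
  if (any(power_w < 0, na.rm = TRUE)) {
    rlang::abort("power must be non-negative", class = "blocktrain_invalid_argument")
  }
  100 * power_w / pi_j_s
}

# Best mean over a fixed-duration contiguous window, in seconds.
# Returns NA if the series is shorter than the window.
best_rolling_mean <- function(x, window_s, sample_period) {
  k <- as.integer(round(window_s / sample_period))
  if (length(x) < k || k < 1L) return(NA_real_)
  means <- stats::filter(x, rep(1 / k, k), sides = 1)
  max(means[k:length(x)])
}

#' VO2max from an incremental-test series
#'
#' VO2max is defined as the highest 60-second rolling mean of oxygen uptake,
#' i.e. the mean of the 12 highest consecutive 5-s samples during the
#' incremental test.
#'
#' @param series A [gas_series()] sampled at 5-s period (any period dividing
#'   60 s is accepted; the window is 60 s, not 12 samples).
#' @return VO2max in mL·min^-1.
#' @export
vo2max_from_series <- function(series) {
  p <- sample_period(series)
  k <- 60 / p
  if (nrow(series) < k) {
    rlang::abort(sprintf("need at least %d samples (60 s) for VO2max", ceiling(k)),
                 class = "blocktrain_insufficient_data")
  }
  best_rolling_mean(series$vo2_ml_min, 60, p)
}

#' Power output at VO2max
#'
#' Mean power over the final 60 seconds of the incremental test before
#' exhaustion ("last minute mean load").
#'
#' @param power_w Power trace (W) at uniform sampling.
#' @param sample_period Seconds per sample.
#' @return Mean power over the last 60 s (W).
#' @export
po_vo2max <- function(power_w, sample_period) {
  k <- as.integer(round(60 / sample_period))
  if (length(power_w) < k) {
    rlang::abort("power trace shorter than 60 s", class = "blocktrain_insufficient_data")
  }
  mean(utils::tail(power_w, k))
}

#' Time spent at or above a fraction of a reference value
#'
#' Counts work-interval samples whose value (oxygen uptake by default, or heart
#' rate) is at or above `fraction * reference`, and converts the count to
#' seconds. Recovery and warm-up segments are excluded: only samples whose
#' segment label marks a work interval are evaluated.
#'
#' @param series A [gas_series()].
#' @param reference Reference maximum (e.g. VO2max in mL·min^-1 or HRmax in bpm).
#' @param fraction Fraction of the reference in (0, 1], default 0.90.
#' @param what Column to threshold, `"vo2_ml_min"` or `"hr_bpm"`.
#' @return Time in seconds.
#' @export
time_at_or_above <- function(series, reference, fraction = 0.90,
                             what = c("vo2_ml_min", "hr_bpm")) {
  what <- match.arg(what)
  stopifnot(reference > 0, fraction > 0, fraction <= 1)
  work <- series[is_work_segment(series$segment), , drop = FALSE]
  if (nrow(work) == 0L) {
    rlang::warn("no work-interval segments in series; returning 0 s")
    return(0)
  }
  sum(work[[what]] >= fraction * reference, na.rm = TRUE) * sample_period(series)
}

#' Aerobic energy turnover over work intervals
#'
#' Computes the average aerobic energy turnover rate (kJ·s^-1) during work
#' intervals from the duration-weighted mean oxygen uptake and RER, and the
#' total turnover (kJ) over the accumulated work-interval duration. With
#' uniform sampling the duration-weighted mean is the sample mean over
#' work-interval samples; the distinction matters (and is preserved) when
#' totals are assembled from per-interval summaries of unequal length.
#'
#' @param series A [gas_series()] with work intervals labeled and RER present.
#' @param body_mass Body mass (kg), used only when `vo2_relative = TRUE`.
#' @param vo2_relative Set `TRUE` if `vo2_ml_min` actually holds relative
#'   uptake (mL·min^-1·kg^-1) to be scaled by `body_mass`.
#' @return A tibble with `pi_j_s` (metabolic power input, J·s^-1), `ge_pct`
#'   (gross efficiency over work intervals, %), `energy_rate_kj_s`,
#'   `energy_total_kj` and `duration_s`.
#' @export
aerobic_energy <- function(series, body_mass = NULL, vo2_relative = FALSE) {
  work <- series[is_work_segment(series$segment), , drop = FALSE]
  if (nrow(work) == 0L) {
    rlang::abort("no work-interval segments labeled", class = "blocktrain_invalid_argument")
  }
  if (anyNA(work$rer)) {
    rlang::abort("RER missing in work intervals; no default is substituted",
                 class = "blocktrain_invalid_argument")
  }
  vo2 <- work$vo2_ml_min
  if (vo2_relative) {
    stopifnot(!is.null(body_mass), body_mass > 0)
    vo2 <- vo2 * body_mass
  }
  dur <- nrow(work) * sample_period(series)
  pi_j_s <- metabolic_power(mean(vo2) / 60000, mean(work$rer))
  tibble::tibble(
    pi_j_s = pi_j_s,
    ge_pct = if (pi_j_s > 0) 100 * mean(work$power_w) / pi_j_s else NA_real_,
    energy_rate_kj_s = pi_j_s / 1000,
    energy_total_kj = pi_j_s / 1000 * dur,
    duration_s = dur
  )
}
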