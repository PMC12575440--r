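# Five-zone endurance-intensity classification, TRIMP scoring, and session /
# week load summaries.

#' Five-zone intensity scheme
#'
#' Zones are defined as percentages of a 40-min maximal cycling trial
#' reference, either its average power output or its average heart rate. The
#' zone cut points are 55, 75, 90 and 105%; bins are contiguous and half-open
#' with each cut assigned to the upper zone (zone 1 = \[0, 55), ..., zone 5 =
#' \[105, Inf)), so every minute of endurance training lands in exactly one
#' zone.
#'
#' @param basis `"percent_po_40min"` (default) or `"percent_hr_40min"`.
#' @param reference The 40-min trial average power (W) or heart rate (bpm);
#'   needed only when classifying absolute values.
#' @param boundaries Four strictly increasing percent cut points.
#' @return A list of class `zone_scheme`.
#' @export
zone_scheme <- function(basis = c("percent_po_40min", "percent_hr_40min"),
                        reference = NA_real_,
                        boundaries = c(55, 75, 90, 105)) {
  basis <- match.arg(basis)
  stopifnot(length(boundaries) == 4L, all(diff(boundaries) > 0))
  structure(list(basis = basis, reference = reference, boundaries = boundaries),
            class = "zone_scheme")
}

#' Classify intensity into a training zone
#'
#' @param intensity_pct Intensity as percent of the scheme's 40-min reference
#'   (non-negative, vectorized).
#' @param scheme A [zone_scheme()].
#' @return Integer zone 1-5.
#' @examples
#' classify_zone(c(54.9, 90, 120))  # 1, 4, 5
#' @export
classify_zone <- function(intensity_pct, scheme = zone_scheme()) {
  if (any(intensity_pct < 0, na.rm = TRUE)) {
    rlang::abort("intensity must be non-negative", class = "blocktrain_invalid_argument")
  }
  findInterval(intensity_pct, scheme$boundaries) + 1L
}

#' Training impulse (TRIMP)
#'
#' Minutes accumulated in each zone weighted by the zone number: 1 min in zone
#' 1 scores 1 TRIMP, 1 min in zone 2 scores 2 TRIMP, and so forth.
#'
#' @param minutes_by_zone Numeric vector of length 5 (minutes in zones 1-5), or
#'   a named vector with names `"1"`..`"5"`.
#' @return TRIMP score (dimensionless).
#' @examples
#' trimp(c(60, 0, 0, 0, 0))   # 60
#' trimp(c(0, 30, 0, 20, 0))  # 140
#' @export
trimp <- function(minutes_by_zone) {
  stopifnot(length(minutes_by_zone) == 5L)
  if (any(minutes_by_zone < 0)) {
    rlang::abort("durations must be non-negative", class = "blocktrain_invalid_argument")
  }
  sum(minutes_by_zone * seq_len(5))
}

#' Summarize an interval session
#'
#' Duration-weighted work-interval means of power, heart rate and oxygen
#' uptake, their fractions of the participant's maxima, time at or above 90%
#' of VO2max and of HRmax, aerobic energy turnover, and perceived exertion.
#' Mirrors the per-session load table of an interval block.
#'
#' @param series A [gas_series()] with work intervals labeled.
#' @param vo2max VO2max (mL·min^-1, absolute).
#' @param hr_max Maximal heart rate (bpm).
#' @param po_vo2max_w Maximal 1-min incremental power (W).
#' @param body_mass Body mass (kg).
#' @param rpe Per-interval Borg 6-20 ratings (averaged arithmetically).
#' @param srpe Session RPE (0-10), passed through.
#' @return A one-row tibble of session-load metrics.
#' @export
summarize_session <- function(series, vo2max, hr_max, po_vo2max_w, body_mass,
                              rpe = NA_real_, srpe = NA_real_) {
  stopifnot(vo2max > 0, hr_max > 0, po_vo2max_w > 0, body_mass > 0)
  work <- series[is_work_segment(series$segment), , drop = FALSE]
  if (nrow(work) == 0L) {
    rlang::abort("no work-interval segments labeled", class = "blocktrain_invalid_argument")
  }
  energy <- aerobic_energy(series)
  tibble::tibble(
    work_duration_s = energy$duration_s,
    po_w = mean(work$power_w),
    po_w_kg = mean(work$power_w) / body_mass,
    pct_po_vo2max = 100 * mean(work$power_w) / po_vo2max_w,
    hr_bpm = mean(work$hr_bpm),
    pct_hr_max = 100 * mean(work$hr_bpm) / hr_max,
    vo2_ml_min_kg = mean(work$vo2_ml_min) / body_mass,
    pct_vo2max = 100 * mean(work$vo2_ml_min) / vo2max,
    t_ge90_vo2max_s = time_at_or_above(series, vo2max, 0.90, "vo2_ml_min"),
    t_ge90_hr_max_s = time_at_or_above(series, hr_max, 0.90, "hr_bpm"),
    energy_rate_kj_s = energy$energy_rate_kj_s,
    energy_total_kj = energy$energy_total_kj,
    rpe = mean(rpe),
    srpe = srpe
  )
}

#' Summarize a training-log week
#'
#' Aggregates free-training log rows into per-zone endurance durations, TRIMP,
#' and pass-through durations for strength/core work. Rows must carry a
#' duration and either an explicit zone or an intensity percent (classified via
#' the scheme); endurance rows with neither are rejected and counted.
#'
#' @param log A data frame with columns `activity` (`"endurance"`,
#'   `"strength"`, `"core"`), `duration_min`, and for endurance rows `zone`
#'   (1-5) or `intensity_pct`.
#' @param scheme A [zone_scheme()] for rows carrying `intensity_pct`.
#' @return A one-row tibble: minutes per zone (`zone1_min`..`zone5_min`),
#'   `trimp`, `strength_min`, `core_min`, `total_min`, `n_rejected`.
#' @export
summarize_week <- function(log, scheme = zone_scheme()) {
  empty <- tibble::tibble(
    zone1_min = 0, zone2_min = 0, zone3_min = 0, zone4_min = 0, zone5_min = 0,
    trimp = 0, strength_min = 0, core_min = 0, total_min = 0, n_rejected = 0L
  )
  if (nrow(log) == 0L) return(empty)
  stopifnot(all(c("activity", "duration_min") %in% names(log)))
  if (!"zone" %in% names(log)) log$zone <- NA_real_
  if (!"intensity_pct" %in% names(log)) log$intensity_pct <- NA_real_

  endur <- log[log$activity == "endurance", , drop = FALSE]
  bad <- is.na(endur$zone) & is.na(endur$intensity_pct)
  if (any(bad)) {
    rlang::warn(sprintf("%d endurance rows lack both zone and intensity; rejected",
                        sum(bad)))
  }
  ok <- endur[!bad, , drop = FALSE]
  z <- ifelse(is.na(ok$zone), classify_zone(ok$intensity_pct, scheme), ok$zone)
  mins <- vapply(1:5, function(k) sum(ok$duration_min[z == k]), numeric(1))
  out <- empty
  out[1, paste0("zone", 1:5, "_min")] <- as.list(mins)
  out$trimp <- trimp(mins)
  out$strength_min <- sum(log$duration_min[log$activity == "strength"])
  out$core_min <- sum(log$duration_min[log$activity == "core"])
  out$total_min <- sum(mins) + out$strength_min + out$core_min
  out$n_rejected <- sum(bad)
  out
}

#' Format minutes as an h:m string
#' @param minutes Duration in minutes.
#' @return Character `"hh:mm"` (minutes rounded).
#' @export
format_hm <- function(minutes) {
  m <- round(minutes)
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}
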