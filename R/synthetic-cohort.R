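# Synthetic cyclist-cohort generator. Latent physiology is drawn per rider;
# every raw record downstream stages consume (step tests, laboratory trials,
# interval-session time series, training logs) is simulated from it with
# configurable measurement noise, so the full measurement chain can be tested
# against known ground truth.

#' Cohort population parameters
#'
#' Means and between-subject SDs of the latent physiology from which riders
#' are drawn. Defaults describe a cohort of well-trained cyclists: VO2max
#' 69.5 (6.0) mL·min^-1·kg^-1, body mass 70.8 (7.9) kg, gross efficiency near
#' 19.7%, fractional utilization at the 4 mmol·L^-1 threshold 79.2 (3.8)% of
#' VO2max. Distributions are normal with physiological clamping (the
#' individual-level shapes are an assumption, not an observation).
#'
#' @param ... Overrides for any default element.
#' @return A named list of class `cohort_params`.
#' @export
cohort_params <- function(...) {
  p <- list(
    body_mass_mean = 70.8, body_mass_sd = 7.9,
    height_mean = 181, height_sd = 7,
    vo2max_rel_mean = 69.5, vo2max_rel_sd = 6.0,
    ge_mean = 0.197, ge_sd = 0.012,
    frac_util_4mmol_mean = 79.2, frac_util_4mmol_sd = 3.8,
    hr_max_mean = 195, hr_max_sd = 7,
    hr_rest = 55,
    vo2_tau_mean = 25, vo2_tau_sd = 4,        # s, first-order VO2 kinetics
    anaerobic_reserve_mean = 1.18, anaerobic_reserve_sd = 0.05,
    po_40min_ratio_mean = 1.00, po_40min_ratio_sd = 0.03,  # PO_40min / PO_4mmol
    po_15min_ratio_mean = 1.07, po_15min_ratio_sd = 0.03,  # PO_15min / PO_40min
    sprint_rel_mean = 13.5, sprint_rel_sd = 1.2,           # W·kg^-1, 10-s power
    la_basal_mean = 0.85, la_basal_sd = 0.15,
    la_rate_mean = 0.025, la_rate_sd = 0.004,              # W^-1
    ge_fatigue_drop_mean = 0.55, ge_fatigue_drop_sd = 0.25, # %-points, tired GE
    prop_female = 1 / 22
  )
  p[names(list(...))] <- list(...)
  structure(p, class = "cohort_params")
}

#' Measurement-noise configuration
#'
#' @param lactate_sd Blood-lactate analyzer SD (mmol·L^-1).
#' @param vo2_cv Relative SD of each VO2 sample (fraction).
#' @param power_cv Relative SD of self-paced power around its target (fraction).
#' @param hr_sd Heart-rate SD (bpm).
#' @return A named list of class `measurement_noise`.
#' @export
measurement_noise <- function(lactate_sd = 0.2, vo2_cv = 0.02,
                              power_cv = 0.01, hr_sd = 2) {
  stopifnot(lactate_sd >= 0, vo2_cv >= 0, power_cv >= 0, hr_sd >= 0)
  structure(list(lactate_sd = lactate_sd, vo2_cv = vo2_cv,
                 power_cv = power_cv, hr_sd = hr_sd),
            class = "measurement_noise")
}

#' True block-effect configuration
#'
#' Per-block true mean percent changes (SD of the between-subject percent
#' change in parentheses conceptually) applied to the latent physiology by
#' [apply_block_effects()]. Gross efficiency changes are in %-points (applied
#' additively to the efficiency percentage). Defaults are the observed block
#' responses of a one-week moderate-intensity (MIT) and a one-week
#' high-intensity (HIT) interval block in well-trained cyclists.
#'
#' @param blocks Named list: one element per block label, each a named list of
#'   `c(mean, sd)` pairs for the outcomes `po_4mmol`, `po_vo2max`, `po_15min`,
#'   `po_10sec`, `vo2max`, `body_mass` (percent) and `ge_pts` (%-points).
#' @param washout_mean,washout_sd Mean/SD (percent) of the latent drift applied
#'   between blocks (regular-training washout period).
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(blocks = NULL, washout_mean = 1.5, washout_sd = 2.0) {
  if (is.null(blocks)) {
    blocks <- list(
      MIT = list(po_4mmol = c(4.5, 4.5), po_vo2max = c(2.4, 4.4),
                 po_15min = c(4.9, 8.7), po_10sec = c(-1.5, 7.3),
                 vo2max = c(1.6, 3.9), ge_pts = c(0.3, 0.6),
                 body_mass = c(0.3, 1.0)),
      HIT = list(po_4mmol = c(2.1, 2.7), po_vo2max = c(3.7, 3.0),
                 po_15min = c(2.8, 5.3), po_10sec = c(1.5, 3.7),
                 vo2max = c(2.4, 3.9), ge_pts = c(0.2, 0.4),
                 body_mass = c(0.3, 1.0))
    )
  }
  for (b in blocks) {
    for (e in b) {
      stopifnot(length(e) == 2L, e[2] >= 0)
      if (e[1] <= -100) {
        rlang::abort("a -100% (or lower) effect would destroy the latent state",
                     class = "blocktrain_invalid_argument")
      }
    }
  }
  structure(list(blocks = blocks, washout_mean = washout_mean,
                 washout_sd = washout_sd),
            class = "effect_config")
}

#' Zero-effect, zero-noise configurations (for recovery tests)
#' @rdname effect_config
#' @export
null_effect_config <- function() {
  zero <- list(po_4mmol = c(0, 0), po_vo2max = c(0, 0), po_15min = c(0, 0),
               po_10sec = c(0, 0), vo2max = c(0, 0), ge_pts = c(0, 0),
               body_mass = c(0, 0))
  effect_config(blocks = list(MIT = zero, HIT = zero),
                washout_mean = 0, washout_sd = 0)
}

# Deterministic sub-stream seed for (master seed, participant, purpose).
# Keeps every participant's stream independent of cohort size, and all seeds
# within 32-bit integer range.
PURPOSE_ID <- c(cohort = 1, effects = 2, washout = 3, step_test = 4,
                sprint = 5, vo2max_test = 6, trial = 7, repeated = 8,
                session = 9, log = 10)
substream_seed <- function(seed, participant = 0L, purpose = "cohort",
                           extra = 0L) {
  pid <- PURPOSE_ID[[purpose]]
  ((seed %% 65011) * 32749 + participant * 1009 + pid * 101 + extra * 7) %%
    2147483647
}

rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# RER as a function of relative intensity (fraction of PO at VO2max):
# climbs from fat-dominated low-intensity exchange toward 1 at maximum.
rer_at_power <- function(power_w, po_vo2max_w) {
  pmin(1.05, pmax(0.72, 0.82 + 0.18 * power_w / po_vo2max_w))
}

# Steady-state VO2 demand (L/s) for a power, under the gross-efficiency model:
# the demand at positive power already includes the resting component (gross,
# not net, efficiency), so efficiency computed from measured VO2 recovers
# ge exactly in the noise-free limit.
vo2_demand_l_s <- function(power_w, ge, po_vo2max_w, rest_vo2_l_s) {
  ifelse(power_w <= 0, rest_vo2_l_s,
         power_w / (ge * (O2_EQ_SLOPE * pmin(rer_at_power(power_w, po_vo2max_w), 1) +
                            O2_EQ_OFFSET)))
}

#' Generate a synthetic cohort with latent physiology
#'
#' Draws `n` riders: identity (id, sex, body mass, height) plus the latent
#' physiological state (`TruePhysiology`) that every simulated measurement is
#' derived from. The latent 4 mmol·L^-1 power is solved from the drawn
#' fractional utilization, efficiency and VO2max so that the lactate curve,
#' gas exchange and thresholds are mutually consistent; the lactate curve is
#' `basal + (4 - basal) * exp(rate * (P - po_4mmol_true))`, which makes
#' `po_4mmol_true` the exact 4 mmol·L^-1 root. Deterministic given `seed`;
#' each rider has an independent sub-stream, so enlarging the cohort never
#' perturbs existing riders.
#'
#' @param n Cohort size (>= 1).
#' @param seed Integer master seed.
#' @param params A [cohort_params()].
#' @return A tibble, one row per rider: `participant_id`, `sex`,
#'   `body_mass_kg`, `height_cm`, and latent columns (`vo2max_rel`, `ge_true`,
#'   `la_basal`, `la_amp`, `la_rate`, `po_4mmol_true_w`, `po_40min_true_w`,
#'   `po_15min_true_w`, `po_vo2max_true_w`, `sprint_true_w_kg`, `hr_max`,
#'   `hr_slope`, `vo2_tau`, `ge_fatigue_drop`, `rest_vo2_l_s`).
#' @export
generate_cohort <- function(n, seed, params = cohort_params()) {
  if (!is.numeric(n) || n < 1) {
    rlang::abort("n must be >= 1", class = "blocktrain_invalid_argument")
  }
  n <- as.integer(n)
  p <- params
  rows <- lapply(seq_len(n), function(i) {
    withr::with_seed(substream_seed(seed, i, "cohort"), {
      sex <- if (stats::runif(1) < p$prop_female) "F" else "M"
      mass <- rnorm_clamped(1, p$body_mass_mean, p$body_mass_sd, 45, 110)
      if (sex == "F") mass <- mass * 0.88
      vo2max_rel <- rnorm_clamped(1, p$vo2max_rel_mean, p$vo2max_rel_sd, 45, 90)
      ge <- rnorm_clamped(1, p$ge_mean, p$ge_sd, 0.15, 0.25)
      frac <- rnorm_clamped(1, p$frac_util_4mmol_mean, p$frac_util_4mmol_sd, 65, 92)
      reserve <- rnorm_clamped(1, p$anaerobic_reserve_mean, p$anaerobic_reserve_sd,
                               1.05, 1.35)
      vo2max_l_s <- vo2max_rel * mass / 60000
      po_vmax <- reserve * ge * (O2_EQ_SLOPE * 1 + O2_EQ_OFFSET) * vo2max_l_s
      # solve P4 = frac * vo2max * ge * eq(rer(P4)) by fixed point (rer(P) is
      # a mild linear function of P; three iterations converge to < 1e-6 W)
      p4 <- 0.67 * po_vmax
      for (k in 1:4) {
        p4 <- (frac / 100) * vo2max_l_s * ge *
          (O2_EQ_SLOPE * pmin(rer_at_power(p4, po_vmax), 1) + O2_EQ_OFFSET)
      }
      la_basal <- rnorm_clamped(1, p$la_basal_mean, p$la_basal_sd, 0.5, 1.5)
      po40 <- p4 * rnorm_clamped(1, p$po_40min_ratio_mean, p$po_40min_ratio_sd,
                                 0.9, 1.1)
      hr_max <- rnorm_clamped(1, p$hr_max_mean, p$hr_max_sd, 170, 215)
      tibble::tibble(
        participant_id = sprintf("P%03d", i),
        sex = sex,
        body_mass_kg = mass,
        height_cm = rnorm_clamped(1, p$height_mean, p$height_sd, 150, 210),
        vo2max_rel = vo2max_rel,
        ge_true = ge,
        la_basal = la_basal,
        la_amp = 4 - la_basal,
        la_rate = rnorm_clamped(1, p$la_rate_mean, p$la_rate_sd, 0.012, 0.045),
        po_4mmol_true_w = p4,
        po_40min_true_w = po40,
        # 15-min power always exceeds the 4 mmol/L power (the trial sits above
        # the maximal metabolic steady state)
        po_15min_true_w = pmax(po40 * rnorm_clamped(1, p$po_15min_ratio_mean,
                                                    p$po_15min_ratio_sd, 0.95, 1.2),
                               1.02 * p4),
        po_vo2max_true_w = po_vmax,
        sprint_true_w_kg = rnorm_clamped(1, p$sprint_rel_mean, p$sprint_rel_sd,
                                         8, 20),
        hr_max = hr_max,
        # calibrated so HR at threshold sits near 88% of maximum
        hr_slope = (0.88 * hr_max - p$hr_rest) / p4,
        hr_rest = p$hr_rest,
        vo2_tau = rnorm_clamped(1, p$vo2_tau_mean, p$vo2_tau_sd, 12, 45),
        ge_fatigue_drop = rnorm_clamped(1, p$ge_fatigue_drop_mean,
                                        p$ge_fatigue_drop_sd, 0, 2),
        rest_vo2_l_s = 0.005 * mass / 60  # ~5 mL/min/kg at rest
      )
    })
  })
  dplyr::bind_rows(rows)
}

# True lactate at a power under the latent curve.
lactate_true <- function(phys, power_w) {
  phys$la_basal + phys$la_amp * exp(phys$la_rate * (power_w - phys$po_4mmol_true_w))
}

# Closed-form power at a lactate level under the latent curve (NA if the flat
# curve never reaches it).
po_at_lactate_true <- function(phys, level = 4) {
  if (phys$la_amp <= 0 || level <= phys$la_basal) return(NA_real_)
  phys$po_4mmol_true_w + log((level - phys$la_basal) / phys$la_amp) / phys$la_rate
}

#' Simulate an incremental lactate-profile step test
#'
#' Runs the step protocol against the rider's latent lactate curve and gas
#' exchange, applying measurement noise, and returns the recorded profile. If
#' the curve never reaches the termination lactate within a safety margin
#' above the rider's maximal power, the profile is flagged non-terminating.
#'
#' @param phys One cohort row (see [generate_cohort()]).
#' @param protocol A [step_protocol()].
#' @param noise A [measurement_noise()].
#' @param seed Integer seed for this test's noise stream.
#' @return A [lactate_profile()].
#' @export
simulate_step_test <- function(phys, protocol = step_protocol(),
                               noise = measurement_noise(), seed = 1) {
  withr::with_seed(seed, {
    power <- lactate <- vo2 <- rer <- hr <- numeric(0)
    prof <- lactate_profile(numeric(0), numeric(0))
    terminated <- TRUE
    repeat {
      p_next <- next_step_power(prof, protocol)
      if (is.na(p_next)) break
      if (p_next > 1.25 * phys$po_vo2max_true_w || length(power) >= 60L) {
        terminated <- FALSE
        break
      }
      la_obs <- max(0, lactate_true(phys, p_next) + stats::rnorm(1, 0, noise$lactate_sd))
      rer_step <- rer_at_power(p_next, phys$po_vo2max_true_w)
      vo2_true <- vo2_demand_l_s(p_next, phys$ge_true, phys$po_vo2max_true_w,
                                 phys$rest_vo2_l_s) * 60000
      vo2_obs <- vo2_true * (1 + stats::rnorm(1, 0, noise$vo2_cv))
      hr_obs <- min(phys$hr_max,
                    phys$hr_rest + phys$hr_slope * p_next +
                      stats::rnorm(1, 0, noise$hr_sd))
      power <- c(power, p_next); lactate <- c(lactate, la_obs)
      vo2 <- c(vo2, vo2_obs); rer <- c(rer, rer_step); hr <- c(hr, hr_obs)
      prof <- lactate_profile(power, lactate, vo2, rer, hr,
                              participant_id = phys$participant_id)
    }
    lactate_profile(power, lactate, vo2, rer, hr,
                    participant_id = phys$participant_id,
                    terminated = terminated)
  })
}

# First-order response of VO2 (L/s) toward a demand trace, discretized at the
# sampling period: x_t = x_{t-1} + (d_t - x_{t-1}) * (1 - exp(-dt/tau)).
first_order_response <- function(demand, tau, dt, x0 = demand[1]) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * demand, a, method = "recursive",
                           init = x0 * 1))
}

#' Simulate the incremental VO2max test
#'
#' One-minute stages (start 250 or 200 W for men depending on ability, 160 W
#' for women; 25/20 W increments) sampled at 5 s, with VO2 following
#' first-order kinetics toward the demand implied by power and efficiency,
#' saturating at the rider's VO2max. The test ends part-way through the stage
#' in which the rider's true maximal 1-min power is reached, so the
#' last-minute mean load recovers it in the noise-free limit.
#'
#' @inheritParams simulate_step_test
#' @return A [gas_series()] at 5-s sampling (all samples labeled `work_1`).
#' @export
simulate_vo2max_test <- function(phys, noise = measurement_noise(), seed = 1) {
  withr::with_seed(seed, {
    female <- identical(phys$sex, "F")
    start <- if (female) 160 else if (phys$po_vo2max_true_w > 330) 250 else 200
    inc <- if (female) 20 else 25
    target <- max(phys$po_vo2max_true_w, start + inc)
    k_last <- ceiling((target - start) / inc)       # stage index reaching target
    stages <- start + inc * (0:k_last)
    frac <- (target - stages[k_last]) / inc          # partial last-stage time
    sec_per_stage <- c(rep(60, k_last), max(5, round(60 * frac / 5) * 5))
    power <- rep(stages, times = sec_per_stage / 5)
    dt <- 5
    demand <- vo2_demand_l_s(power, phys$ge_true, phys$po_vo2max_true_w,
                             phys$rest_vo2_l_s)
    vo2max_l_s <- phys$vo2max_rel * phys$body_mass_kg / 60000
    vo2 <- first_order_response(pmin(demand, vo2max_l_s), phys$vo2_tau, dt,
                                x0 = phys$rest_vo2_l_s * 3)
    vo2_ml_min <- vo2 * 60000 * (1 + stats::rnorm(length(vo2), 0, noise$vo2_cv))
    hr <- pmin(phys$hr_max,
               phys$hr_rest + phys$hr_slope * power +
                 stats::rnorm(length(power), 0, noise$hr_sd))
    gas_series(t_s = seq_along(power) * dt, power_w = power,
               vo2_ml_min = vo2_ml_min,
               rer = rer_at_power(power, phys$po_vo2max_true_w),
               hr_bpm = hr, segment = "work_1", sample_period = dt)
  })
}

#' Simulate the 10-s all-out sprint
#'
#' A 12-s trace at 1-s sampling whose best 10-s rolling mean equals the
#' rider's true sprint power in the noise-free limit (power peaks early and
#' fades, as in a seated sprint).
#'
#' @inheritParams simulate_step_test
#' @return A [gas_series()] (power only) at 1-s sampling.
#' @export
simulate_sprint <- function(phys, noise = measurement_noise(), seed = 1) {
  withr::with_seed(seed, {
    shape <- c(0.85, 1.10, 1.15, 1.12, 1.08, 1.04, 1.00, 0.97, 0.94, 0.91,
               0.88, 0.85)
    best <- max(stats::filter(shape, rep(1 / 10, 10), sides = 1), na.rm = TRUE)
    target <- phys$sprint_true_w_kg * phys$body_mass_kg / best
    pw <- target * shape * (1 + stats::rnorm(length(shape), 0, noise$power_cv))
    gas_series(t_s = seq_along(shape), power_w = pw, segment = "work_1",
               sample_period = 1)
  })
}

#' Simulate the 15-min maximal trial
#'
#' Self-paced power around the rider's true 15-min power (small zero-mean
#' pacing drift plus sample noise), VO2 by first-order kinetics capped at
#' VO2max, sampled at 5 s.
#'
#' @inheritParams simulate_step_test
#' @return A [gas_series()] at 5-s sampling.
#' @export
simulate_trial_15min <- function(phys, noise = measurement_noise(), seed = 1) {
  withr::with_seed(seed, {
    dt <- 5
    n <- 900 / dt
    tt <- seq_len(n) * dt
    pacing <- 1 + 0.03 * cos(2 * pi * tt / 900)     # fast start, mid-trial dip
    pacing <- pacing / mean(pacing)
    power <- phys$po_15min_true_w * pacing *
      (1 + stats::rnorm(n, 0, noise$power_cv))
    demand <- vo2_demand_l_s(power, phys$ge_true, phys$po_vo2max_true_w,
                             phys$rest_vo2_l_s)
    vo2max_l_s <- phys$vo2max_rel * phys$body_mass_kg / 60000
    vo2 <- first_order_response(pmin(demand, vo2max_l_s), phys$vo2_tau, dt,
                                x0 = phys$rest_vo2_l_s * 4)
    vo2_ml_min <- vo2 * 60000 * (1 + stats::rnorm(n, 0, noise$vo2_cv))
    hr <- pmin(phys$hr_max,
               phys$hr_rest + phys$hr_slope * power + stats::rnorm(n, 0, noise$hr_sd))
    gas_series(t_s = tt, power_w = power, vo2_ml_min = vo2_ml_min,
               rer = rer_at_power(power, phys$po_vo2max_true_w), hr_bpm = hr,
               segment = "work_1", sample_period = dt)
  })
}

#' Repeat the third- and second-last profile steps in the semi-fatigued state
#'
#' After the 30-min bout at the 2 mmol·L^-1 power, gross efficiency is reduced
#' by the rider's latent fatigue drop; the two steps are re-ridden at the same
#' powers and steady-state gas exchange is recorded.
#'
#' @param profile The fresh-state [lactate_profile()] of the same test.
#' @inheritParams simulate_step_test
#' @return A two-row [lactate_profile()]-shaped record (third-last step first),
#'   or `NULL` when the profile has fewer than three steps.
#' @export
simulate_repeated_steps <- function(phys, profile, noise = measurement_noise(),
                                    seed = 1) {
  if (nrow(profile) < 3L) return(NULL)
  withr::with_seed(seed, {
    pw <- profile$power_w[nrow(profile) - c(2L, 1L)]
    ge_tired <- max(0.12, phys$ge_true - phys$ge_fatigue_drop / 100)
    rer_step <- rer_at_power(pw, phys$po_vo2max_true_w)
    vo2_true <- vo2_demand_l_s(pw, ge_tired, phys$po_vo2max_true_w,
                               phys$rest_vo2_l_s) * 60000
    vo2_obs <- vo2_true * (1 + stats::rnorm(2, 0, noise$vo2_cv))
    la_obs <- pmax(0, lactate_true(phys, pw) + 0.3 +
                     stats::rnorm(2, 0, noise$lactate_sd))
    hr <- pmin(phys$hr_max, phys$hr_rest + phys$hr_slope * pw + 4 +
                 stats::rnorm(2, 0, noise$hr_sd))
    lactate_profile(pw, la_obs, vo2_obs, rer_step, hr,
                    participant_id = phys$participant_id, terminated = FALSE)
  })
}

#' Interval-session prescriptions
#'
#' The moderate-intensity (MIT) shapes are continuous work intervals (7 x 10,
#' 6 x 12 or 5 x 14 min with 2.5/3/3.5-min recoveries) at a fraction of the
#' 40-min maximal power; the high-intensity (HIT) shape is 5 x 8.75-min blocks
#' of 30-s work at ~118% / 15-s relief at ~60% of the 40-min power with 3-min
#' recoveries.
#'
#' @param shape One of `"mit_7x10"`, `"mit_6x12"`, `"mit_5x14"`,
#'   `"hit_5x8.75"`.
#' @param mit_intensity Work fraction of the 40-min power for MIT intervals
#'   (effort-guided sessions sit just below the 40-min power).
#' @param hit_work,hit_relief Guiding work/relief fractions for the 30/15-s
#'   pattern.
#' @param hit_effort Multiplier on the guiding HIT fractions: the pattern is
#'   RPE-guided (16-18), and riders settle above the nominal guidance.
#' @return A list of class `session_prescription`.
#' @export
session_prescription <- function(shape, mit_intensity = 0.97,
                                 hit_work = 1.18, hit_relief = 0.60,
                                 hit_effort = 1.10) {
  shapes <- list(
    "mit_7x10" = list(kind = "mit", n = 7, work_s = 600, rec_s = 150),
    "mit_6x12" = list(kind = "mit", n = 6, work_s = 720, rec_s = 180),
    "mit_5x14" = list(kind = "mit", n = 5, work_s = 840, rec_s = 210),
    "hit_5x8.75" = list(kind = "hit", n = 5, work_s = 525, rec_s = 180)
  )
  if (!shape %in% names(shapes)) {
    rlang::abort(sprintf("unknown prescription shape '%s'", shape),
                 class = "blocktrain_invalid_argument")
  }
  structure(c(shapes[[shape]],
              list(shape = shape, mit_intensity = mit_intensity,
                   hit_work = hit_work * hit_effort,
                   hit_relief = hit_relief * hit_effort)),
            class = "session_prescription")
}

#' The session plans of the two training blocks
#'
#' MIT: six sessions over seven days (7x10, 6x12, 5x14, 7x10, 5x14, 6x12 min);
#' HIT: five sessions of 5 x 8.75 min. Total work-interval time is 424 min for
#' MIT and 218.75 min for HIT.
#'
#' @param block `"MIT"` or `"HIT"`.
#' @return Character vector of prescription shapes, in session order.
#' @export
block_sessions <- function(block = c("MIT", "HIT")) {
  block <- match.arg(block)
  if (block == "MIT") {
    c("mit_7x10", "mit_6x12", "mit_5x14", "mit_7x10", "mit_5x14", "mit_6x12")
  } else {
    rep("hit_5x8.75", 5)
  }
}

#' Total prescribed work-interval minutes of a block
#' @param shapes Prescription shapes, e.g. from [block_sessions()].
#' @return Minutes of work-interval time.
#' @export
block_work_minutes <- function(shapes) {
  sum(vapply(shapes, function(s) {
    p <- session_prescription(s)
    p$n * p$work_s / 60
  }, numeric(1)))
}

#' Simulate an interval training session
#'
#' Builds the 10-s-sampled power prescription (15-min progressive warm-up,
#' 5-min rest, then the work/recovery pattern), runs VO2 through first-order
#' kinetics toward the efficiency-implied demand (saturating at VO2max), heart
#' rate through slower first-order kinetics toward its power-implied
#' steady state (saturating at HRmax), and emits per-interval RPE around the
#' block's target effort.
#'
#' @param phys One cohort row.
#' @param prescription A [session_prescription()] (or a shape name).
#' @param noise A [measurement_noise()].
#' @param seed Integer seed.
#' @param intensity_jitter_sd Between-session SD of the effort-guided intensity
#'   scaling (RPE-guided sessions are not power-controlled).
#' @return A list: `series` (a [gas_series()]), `rpe` (per-interval Borg 6-20),
#'   `srpe` (session RPE, 0-10).
#' @export
simulate_session <- function(phys, prescription, noise = measurement_noise(),
                             seed = 1, intensity_jitter_sd = 0.04) {
  if (is.character(prescription)) prescription <- session_prescription(prescription)
  stopifnot(inherits(prescription, "session_prescription"))
  withr::with_seed(seed, {
    # the true power pattern is built on a 5-s grid (the 30/15-s HIT cycle is
    # a 45-s square wave: 6 work + 3 relief samples); the mixing-chamber
    # measurement is then emitted on the 10-s grid by averaging sample pairs
    dt <- 5
    po40 <- phys$po_40min_true_w
    scale <- exp(stats::rnorm(1, 0, intensity_jitter_sd))
    power <- c(seq(0.35, 0.65, length.out = 180) * po40,   # 15-min warm-up
               rep(0, 60))                                 # 5-min rest
    segment <- c(rep("warmup", 180), rep("rest", 60))
    for (k in seq_len(prescription$n)) {
      nw <- prescription$work_s / dt
      wk <- scale * po40 * (if (prescription$kind == "mit") {
        rep(prescription$mit_intensity, nw)
      } else {
        rep(c(rep(prescription$hit_work, 6), rep(prescription$hit_relief, 3)),
            length.out = nw)
      })
      power <- c(power, wk)
      segment <- c(segment, rep(sprintf("work_%d", k), nw))
      if (k < prescription$n) {
        nrec <- prescription$rec_s / dt
        power <- c(power, rep(0.4 * po40, nrec))
        segment <- c(segment, rep(sprintf("recovery_%d", k), nrec))
      }
    }
    n <- length(power)
    power_true <- power * (1 + stats::rnorm(n, 0, noise$power_cv))
    demand <- vo2_demand_l_s(power_true, phys$ge_true, phys$po_vo2max_true_w,
                             phys$rest_vo2_l_s)
    vo2max_l_s <- phys$vo2max_rel * phys$body_mass_kg / 60000
    vo2 <- first_order_response(pmin(demand, vo2max_l_s), phys$vo2_tau, dt,
                                x0 = phys$rest_vo2_l_s * 2)
    hr_ss <- pmin(phys$hr_max, phys$hr_rest + phys$hr_slope * power_true)
    hr <- first_order_response(hr_ss, 45, dt, x0 = phys$hr_rest + 20)

    # downsample to the 10-s measurement grid (average consecutive 5-s pairs)
    if (n %% 2L == 1L) {  # pad with a copy of the last sample
      power_true <- c(power_true, power_true[n])
      vo2 <- c(vo2, vo2[n]); hr <- c(hr, hr[n])
      segment <- c(segment, segment[n])
      n <- n + 1L
    }
    pair_mean <- function(x) (x[seq(1, n, by = 2)] + x[seq(2, n, by = 2)]) / 2
    m <- n / 2L
    power10 <- pair_mean(power_true)
    vo2_10 <- pair_mean(vo2) * 60000 * (1 + stats::rnorm(m, 0, noise$vo2_cv))
    hr10 <- pmin(phys$hr_max, pair_mean(hr) + stats::rnorm(m, 0, noise$hr_sd))
    seg10 <- segment[seq(1, n, by = 2)]

    rpe_target <- if (prescription$kind == "mit") 14.5 else 17.1
    srpe_target <- if (prescription$kind == "mit") 5.0 else 6.9
    list(
      series = gas_series(t_s = seq_len(m) * 10, power_w = power10,
                          vo2_ml_min = vo2_10,
                          rer = rer_at_power(power10, phys$po_vo2max_true_w),
                          hr_bpm = hr10, segment = seg10, sample_period = 10),
      rpe = round(rpe_target + stats::rnorm(prescription$n, 0, 0.4), 1),
      srpe = round(srpe_target + stats::rnorm(1, 0, 1.0), 1)
    )
  })
}

#' Apply true block effects to the latent physiology
#'
#' Draws each rider's true percent change per outcome from the block's
#' configured mean/SD and scales the corresponding latent parameters:
#' `po_4mmol` scales the lactate-curve root (and the 40-min/15-min powers tied
#' to it through their ratios), `po_vo2max`, `po_10sec`, `vo2max` and
#' `body_mass` scale their latent values, and `ge_pts` shifts efficiency in
#' %-points. Deterministic given `seed`; the drawn truths are returned so
#' recovery can be checked.
#'
#' @param cohort Cohort tibble (see [generate_cohort()]).
#' @param config An [effect_config()].
#' @param block Block label, must exist in `config$blocks`.
#' @param seed Integer master seed (sub-streams per rider).
#' @return A list: `cohort` (post-block latent state) and `truth` (tibble of
#'   drawn per-rider percent changes per outcome).
#' @export
apply_block_effects <- function(cohort, config, block, seed) {
  if (!block %in% names(config$blocks)) {
    rlang::abort(sprintf("block '%s' missing from effect config", block),
                 class = "blocktrain_invalid_argument")
  }
  eff <- config$blocks[[block]]
  post <- cohort
  truths <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    draws <- withr::with_seed(
      substream_seed(seed, i, "effects",
                     extra = match(block, names(config$blocks))), {
      vapply(eff, function(e) stats::rnorm(1, e[1], e[2]), numeric(1))
    })
    if (any(draws[setdiff(names(draws), "ge_pts")] <= -100)) {
      rlang::abort("drawn effect at or below -100%",
                   class = "blocktrain_invalid_argument")
    }
    p4_scale <- 1 + draws[["po_4mmol"]] / 100
    post$po_4mmol_true_w[i] <- cohort$po_4mmol_true_w[i] * p4_scale
    post$po_40min_true_w[i] <- cohort$po_40min_true_w[i] * p4_scale
    post$po_15min_true_w[i] <- cohort$po_15min_true_w[i] *
      (1 + draws[["po_15min"]] / 100)
    post$po_vo2max_true_w[i] <- cohort$po_vo2max_true_w[i] *
      (1 + draws[["po_vo2max"]] / 100)
    post$sprint_true_w_kg[i] <- cohort$sprint_true_w_kg[i] *
      (1 + draws[["po_10sec"]] / 100)
    post$vo2max_rel[i] <- cohort$vo2max_rel[i] * (1 + draws[["vo2max"]] / 100)
    post$ge_true[i] <- min(0.25, max(0.15,
      cohort$ge_true[i] + draws[["ge_pts"]] / 100))
    post$body_mass_kg[i] <- cohort$body_mass_kg[i] *
      (1 + draws[["body_mass"]] / 100)
    truths[[i]] <- tibble::tibble(
      participant_id = cohort$participant_id[i], block = block,
      outcome = names(draws), true_pct = unname(draws)
    )
  }
  list(cohort = post, truth = dplyr::bind_rows(truths))
}

# Latent drift over the regular-training washout between blocks.
apply_washout <- function(cohort, config, seed) {
  drift_fields <- c("po_4mmol_true_w", "po_40min_true_w", "po_15min_true_w",
                    "po_vo2max_true_w", "vo2max_rel")
  post <- cohort
  for (i in seq_len(nrow(cohort))) {
    d <- withr::with_seed(substream_seed(seed, i, "washout"),
                          stats::rnorm(1, config$washout_mean, config$washout_sd))
    for (f in drift_fields) post[[f]][i] <- cohort[[f]][i] * (1 + d / 100)
  }
  post
}

#' Simulate a full test battery and measure it
#'
#' Simulates the prolonged test (lactate profile, sprint, incremental VO2max
#' test, repeated steps after the 30-min bout, 15-min trial) for one rider at
#' one timepoint and runs the measurement chain ([assemble_battery()]) on the
#' simulated raw records.
#'
#' @param phys One cohort row.
#' @param seed Integer seed for the battery's noise streams.
#' @param noise A [measurement_noise()].
#' @param block,timepoint Labels carried into the result.
#' @return A one-row battery tibble (see [assemble_battery()]).
#' @export
simulate_battery <- function(phys, seed, noise = measurement_noise(),
                             block = NA_character_, timepoint = NA_character_) {
  profile <- simulate_step_test(phys, noise = noise,
                                seed = substream_seed(seed, 1, "step_test"))
  sprint <- simulate_sprint(phys, noise, substream_seed(seed, 1, "sprint"))
  vtest <- simulate_vo2max_test(phys, noise, substream_seed(seed, 1, "vo2max_test"))
  rep_steps <- simulate_repeated_steps(phys, profile, noise,
                                       substream_seed(seed, 1, "repeated"))
  trial <- simulate_trial_15min(phys, noise, substream_seed(seed, 1, "trial"))
  assemble_battery(profile, sprint, vtest, rep_steps, trial,
                   body_mass = phys$body_mass_kg,
                   participant_id = phys$participant_id,
                   block = block, timepoint = timepoint)
}

#' Simulate the full two-block study and measure every battery
#'
#' Generates a cohort, runs the first block (MIT) with its configured true
#' effects, a washout drift, then the second block (HIT), measuring a full
#' test battery before and after each block. This is the in-memory end-to-end
#' pipeline; [simulate_dataset()] writes the same content to delimited files.
#'
#' @param n Cohort size.
#' @param seed Integer master seed; fixes cohort, effects and all noise.
#' @param effects An [effect_config()].
#' @param noise A [measurement_noise()].
#' @param params A [cohort_params()].
#' @return A list: `cohort` (baseline latent state), `batteries` (tibble of
#'   measured battery results, one row per rider x block x timepoint),
#'   `truth` (drawn true percent changes per rider x block x outcome).
#' @export
simulate_study <- function(n = 22, seed = 1, effects = effect_config(),
                           noise = measurement_noise(),
                           params = cohort_params()) {
  cohort <- generate_cohort(n, seed, params)
  out <- list()
  truth <- list()
  state <- cohort
  for (b in c("MIT", "HIT")) {
    eff <- apply_block_effects(state, effects, b, seed)
    for (i in seq_len(n)) {
      tp_seed <- function(tp) substream_seed(seed, i, "session",
                                             extra = 13 * match(b, c("MIT", "HIT")) +
                                               match(tp, c("pre", "post")))
      out[[length(out) + 1L]] <-
        simulate_battery(state[i, ], tp_seed("pre"), noise, b, "pre")
      out[[length(out) + 1L]] <-
        simulate_battery(eff$cohort[i, ], tp_seed("post"), noise, b, "post")
    }
    truth[[b]] <- eff$truth
    if (b == "MIT") state <- apply_washout(eff$cohort, effects, seed)
  }
  list(cohort = cohort, batteries = dplyr::bind_rows(out),
       truth = dplyr::bind_rows(truth))
}
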