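# Shared fixtures: all built in code at test time.

# A constant-value gas series.
const_series <- function(n, vo2 = 4000, power = 250, rer = 0.95, hr = 160,
                         period = 5, segment = "work_1") {
  gas_series(t_s = seq_len(n) * period, power_w = power, vo2_ml_min = vo2,
             rer = rer, hr_bpm = hr, segment = segment, sample_period = period)
}

# Exhaustive-scan oracle for the best mean over k consecutive samples.
brute_best_window <- function(x, k) {
  if (length(x) < k) return(NA_real_)
  max(vapply(seq_len(length(x) - k + 1), function(i) mean(x[i:(i + k - 1)]),
             numeric(1)))
}

# Piecewise-linear oracle: dense-grid evaluation of lactate-vs-power, then the
# first grid power whose interpolated lactate reaches the level.
brute_po_at_level <- function(power, lactate, level, grid_n = 2e5) {
  g <- seq(min(power), max(power), length.out = grid_n)
  la <- approx(power, lactate, xout = g, ties = "ordered")$y
  idx <- which(la >= level)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1) return(g[1])
  # refine by solving the segment linearly between the two grid points
  x0 <- g[idx - 1]; x1 <- g[idx]; y0 <- la[idx - 1]; y1 <- la[idx]
  x0 + (level - y0) * (x1 - x0) / (y1 - y0)
}

# A rider with fixed latent physiology (no sampling), for targeted tests.
fixed_phys <- function(ge = 0.20, vo2max_rel = 70, mass = 70,
                       p4 = 280, tau = 25, la_basal = 0.8, la_rate = 0.025) {
  tibble::tibble(
    participant_id = "PX", sex = "M", body_mass_kg = mass, height_cm = 180,
    vo2max_rel = vo2max_rel, ge_true = ge, la_basal = la_basal,
    la_amp = 4 - la_basal, la_rate = la_rate,
    po_4mmol_true_w = p4, po_40min_true_w = p4,
    po_15min_true_w = 1.07 * p4,
    po_vo2max_true_w = 1.18 * ge * 21730 * (vo2max_rel * mass / 60000),
    sprint_true_w_kg = 13.5, hr_max = 195, hr_slope = (0.88 * 195 - 55) / p4,
    hr_rest = 55, vo2_tau = tau, ge_fatigue_drop = 0.6,
    rest_vo2_l_s = 0.005 * mass / 60
  )
}

no_noise <- function() measurement_noise(lactate_sd = 0, vo2_cv = 0,
                                         power_cv = 0, hr_sd = 0)
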