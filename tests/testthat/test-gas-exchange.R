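test_that("metabolic power follows the energetic-equivalent line", {
  expect_equal(metabolic_power(1.0, 1.0), 21730)
  # 4 L/min at RER 0.90: (4840*0.9 + 16890)/15
  expect_equal(metabolic_power(4 / 60, 0.90), 21246 / 15, tolerance = 1e-12)
  expect_equal(metabolic_power(0, 0.8), 0)
  # RER above 1 clamps to the RER-1 equivalent
  expect_equal(metabolic_power(1, 1.08), metabolic_power(1, 1.0))
  expect_error(metabolic_power(-0.1, 0.9), class = "blocktrain_invalid_argument")
  expect_error(metabolic_power(1, 1.4), class = "blocktrain_invalid_argument")
})

test_that("metabolic power is linear in vo2 and non-decreasing in RER", {
  vo2 <- seq(0, 0.1, length.out = 11)
  expect_equal(metabolic_power(2 * vo2, 0.85), 2 * metabolic_power(vo2, 0.85))
  rers <- seq(0.6, 1.0, by = 0.05)
  pis <- metabolic_power(0.07, rers)
  expect_true(all(diff(pis) > 0))
})

test_that("gross efficiency is mechanical over metabolic power", {
  expect_equal(gross_efficiency(250, 1250), 20.0)
  expect_equal(gross_efficiency(280, metabolic_power(4 / 60, 0.90)),
               100 * 280 / (21246 / 15), tolerance = 1e-12)
  expect_equal(gross_efficiency(0, 1000), 0)
  expect_error(gross_efficiency(250, 0), class = "blocktrain_invalid_argument")
})

test_that("VO2max is the best 60-s rolling mean", {
  expect_equal(vo2max_from_series(const_series(100, vo2 = 4000)), 4000)
  # a 12-sample plateau of 4500 embedded in 4000s
  v <- rep(4000, 60); v[21:32] <- 4500
  s <- gas_series(seq_along(v) * 5, 250, v, 0.95, 160, "work_1", 5)
  expect_equal(vo2max_from_series(s), 4500)
  expect_error(vo2max_from_series(const_series(11)),
               class = "blocktrain_insufficient_data")
})

test_that("rolling-window VO2max equals the exhaustive-scan oracle", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(12:200, 1)
      v <- runif(n, 3000, 5000)
      s <- gas_series(seq_len(n) * 5, 250, v, 0.95, 160, "work_1", 5)
      expect_equal(vo2max_from_series(s), brute_best_window(v, 12),
                   tolerance = 1e-9)
    }
  })
})

test_that("power at VO2max is the final-minute mean load", {
  pw <- c(rep(200, 60), rep(250, 6), rep(275, 6))  # 5-s samples, 30+30 s last
  expect_equal(po_vo2max(pw, 5), 262.5)
  expect_equal(po_vo2max(rep(300, 20), 5), 300)
  expect_error(po_vo2max(rep(300, 5), 5), class = "blocktrain_insufficient_data")
})

test_that("time at or above a threshold counts work-interval samples only", {
  v <- c(rep(3000, 5), rep(4600, 7), rep(3000, 4))
  seg <- c(rep("warmup", 5), rep("work_1", 7), rep("recovery_1", 4))
  s <- gas_series(seq_along(v) * 10, 250, v, 0.95, 160, seg, 10)
  expect_equal(time_at_or_above(s, 5000, 0.90), 70)   # 7 samples x 10 s
  expect_equal(time_at_or_above(s, 6000, 0.90), 0)
  # warm-up samples above threshold never count
  expect_equal(time_at_or_above(s, 3000, 0.90), 70)
  s2 <- gas_series(1:5 * 10, 250, 4000, 0.95, 160, "warmup", 10)
  expect_warning(out <- time_at_or_above(s2, 4000, 0.9), "no work")
  expect_equal(out, 0)
})

test_that("aerobic energy turnover matches hand computation and is definitional", {
  # VO2 54 mL/min/kg at 70.8 kg, RER 0.99, 72 min of work intervals
  n <- 4320 / 10
  s <- gas_series(seq_len(n) * 10, 260, 54 * 70.8, 0.99, 165, "work_1", 10)
  e <- aerobic_energy(s)
  rate_hand <- (54 * 70.8 / 60000) * (4840 * 0.99 + 16890) / 1000
  expect_equal(e$energy_rate_kj_s, rate_hand, tolerance = 1e-12)
  expect_equal(e$energy_total_kj, rate_hand * 4320, tolerance = 1e-12)
  expect_equal(e$duration_s, 4320)
  # zero uptake gives zero turnover
  s0 <- gas_series(1:20 * 10, 0, 0, 0.9, 100, "work_1", 10)
  expect_equal(aerobic_energy(s0)$energy_rate_kj_s, 0)
  expect_error(aerobic_energy(gas_series(1:20, 250, 4000, NA, 150, "work_1", 10)),
               class = "blocktrain_invalid_argument")
})

test_that("work-interval energy is additive only under duration weighting", {
  withr::with_seed(7, {
    # two work intervals of unequal length and different intensity
    v <- c(runif(30, 3500, 4000), runif(90, 4500, 5000))
    seg <- c(rep("work_1", 30), rep("work_2", 90))
    s <- gas_series(seq_along(v) * 10, 250, v, 0.95, 160, seg, 10)
    whole <- aerobic_energy(s)
    per_interval <- lapply(c("work_1", "work_2"), function(w) {
      keep <- s[s$segment == w, ]
      attr(keep, "sample_period") <- 10
      class(keep) <- class(s)
      aerobic_energy(keep)
    })
    part_sum <- sum(vapply(per_interval, function(p) p$energy_total_kj, numeric(1)))
    expect_equal(part_sum, whole$energy_total_kj, tolerance = 1e-12)
    # an unweighted average of per-interval rates would get the session wrong
    naive_rate <- mean(vapply(per_interval, function(p) p$energy_rate_kj_s,
                              numeric(1)))
    expect_gt(abs(naive_rate * whole$duration_s - whole$energy_total_kj), 10)
  })
})
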