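test_that("cohort generation is deterministic and hits configured moments", {
  co <- generate_cohort(22, seed = 1)
  expect_equal(nrow(co), 22)
  expect_equal(length(unique(co$participant_id)), 22)
  expect_lt(abs(mean(co$vo2max_rel) - 69.5), 2 * 6.0 / sqrt(22) + 1e-9)
  expect_identical(generate_cohort(1, seed = 7), generate_cohort(1, seed = 7))
  # law of large numbers against the configured mean
  big <- generate_cohort(1000, seed = 3)
  expect_lt(abs(mean(big$vo2max_rel) - 69.5), 0.5)
  expect_lt(abs(mean(big$body_mass_kg) - 70.8), 1.0)
  expect_error(generate_cohort(0, seed = 1), class = "blocktrain_invalid_argument")
})

test_that("enlarging the cohort never perturbs existing riders", {
  small <- generate_cohort(5, seed = 11)
  large <- generate_cohort(12, seed = 11)
  expect_identical(as.data.frame(small), as.data.frame(large[1:5, ]))
})

test_that("latent physiology satisfies its invariants and ordering", {
  co <- generate_cohort(300, seed = 4)
  expect_true(all(co$ge_true >= 0.15 & co$ge_true <= 0.25))
  expect_true(all(co$la_amp > 0 & co$la_rate > 0 & co$vo2_tau > 0))
  expect_true(all(co$body_mass_kg > 0))
  # threshold < 15-min power < maximal incremental power, for every rider
  expect_true(all(co$po_4mmol_true_w < co$po_15min_true_w))
  expect_true(all(co$po_15min_true_w < co$po_vo2max_true_w))
})

test_that("VO2 kinetics follow the first-order response", {
  # constant demand: converged within 1% after five time constants
  d <- rep(4.0, 200)
  x <- blocktrain:::first_order_response(d, tau = 30, dt = 5, x0 = 1)
  i5 <- ceiling(5 * 30 / 5)
  expect_lt(abs(x[i5] - 4.0) / 4.0, 0.01)
  expect_lt(abs(x[200] - 4.0), 1e-6)
  # square wave equals the piecewise analytic exponential at every sample
  tau <- 30; dt <- 5
  demand <- rep(c(rep(4, 24), rep(2, 24)), 3)
  x <- blocktrain:::first_order_response(demand, tau, dt, x0 = 2)
  a <- exp(-dt / tau)
  analytic <- numeric(length(demand)); prev <- 2
  for (i in seq_along(demand)) {
    analytic[i] <- demand[i] + (prev - demand[i]) * a
    prev <- analytic[i]
  }
  expect_equal(x, analytic, tolerance = 1e-12)
})

test_that("sessions are deterministic and HIT runs hotter than MIT", {
  phys <- fixed_phys()
  s1 <- simulate_session(phys, "mit_6x12", seed = 61)
  s2 <- simulate_session(phys, "mit_6x12", seed = 61)
  expect_identical(as.data.frame(s1$series), as.data.frame(s2$series))
  expect_error(simulate_session(phys, "hit_4x4"),
               class = "blocktrain_invalid_argument")

  co <- generate_cohort(6, seed = 62)
  vm <- co$vo2max_rel * co$body_mass_kg
  for (i in 1:6) {
    mit <- simulate_session(co[i, ], "mit_6x12", seed = 70 + i,
                            intensity_jitter_sd = 0)
    hit <- simulate_session(co[i, ], "hit_5x8.75", seed = 80 + i,
                            intensity_jitter_sd = 0)
    sm <- summarize_session(mit$series, vm[i], co$hr_max[i],
                            co$po_vo2max_true_w[i], co$body_mass_kg[i])
    sh <- summarize_session(hit$series, vm[i], co$hr_max[i],
                            co$po_vo2max_true_w[i], co$body_mass_kg[i])
    # work intervals at higher fraction of VO2max, and more time >= 90%
    expect_gt(sh$pct_vo2max, sm$pct_vo2max)
    expect_gte(sh$t_ge90_vo2max_s, sm$t_ge90_vo2max_s)
  }
})

test_that("block effects scale the latent state and recover their means", {
  co <- generate_cohort(3, seed = 63)
  # null effects leave the state untouched
  eff0 <- apply_block_effects(co, null_effect_config(), "MIT", seed = 63)
  expect_equal(as.data.frame(eff0$cohort), as.data.frame(co), tolerance = 1e-12)
  expect_error(apply_block_effects(co, effect_config(), "XIT", seed = 1),
               class = "blocktrain_invalid_argument")
  expect_error(effect_config(blocks = list(
    MIT = list(po_4mmol = c(-100, 0), po_vo2max = c(0, 0), po_15min = c(0, 0),
               po_10sec = c(0, 0), vo2max = c(0, 0), ge_pts = c(0, 0),
               body_mass = c(0, 0)))),
    class = "blocktrain_invalid_argument")

  # a +4.5 (4.5)% threshold effect is recovered from the drawn truths, n = 200
  co2 <- generate_cohort(200, seed = 64)
  eff <- apply_block_effects(co2, effect_config(), "MIT", seed = 64)
  drawn <- eff$truth$true_pct[eff$truth$outcome == "po_4mmol"]
  expect_lt(abs(mean(drawn) - 4.5), 1.0)
  applied <- 100 * (eff$cohort$po_4mmol_true_w / co2$po_4mmol_true_w - 1)
  expect_equal(applied, drawn, tolerance = 1e-9)
})

test_that("full study simulation is deterministic given the master seed", {
  a <- simulate_study(n = 2, seed = 65)
  b <- simulate_study(n = 2, seed = 65)
  expect_identical(as.data.frame(a$batteries), as.data.frame(b$batteries))
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("protocol arithmetic: block work-interval durations", {
  expect_equal(block_work_minutes(block_sessions("MIT")), 424)   # 7 h 4 min
  expect_equal(format_hm(block_work_minutes(block_sessions("MIT"))), "07:04")
  expect_equal(block_work_minutes(block_sessions("HIT")), 218.75)
})
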