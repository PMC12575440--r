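test_that("step protocol increments coarse, then fine, then stops", {
  spec <- step_protocol()
  expect_equal(next_step_power(lactate_profile(numeric(0), numeric(0)), spec), 125)
  expect_equal(step_protocol(high_start = TRUE)$start_power, 175)
  # all readings below 2: coarse 50 W
  expect_equal(next_step_power(lactate_profile(c(125, 175, 225), c(1.1, 1.4, 1.9)),
                               spec), 275)
  # fine rule engages after the first reading at or above 2
  expect_equal(next_step_power(lactate_profile(c(125, 175, 225), c(1.2, 1.8, 2.3)),
                               spec), 250)
  # termination at or above 4
  expect_true(is.na(next_step_power(
    lactate_profile(c(125, 175, 225, 250), c(1.2, 1.8, 2.3, 4.1)), spec)))
  expect_error(lactate_profile(c(225, 175), c(1, 2)),
               class = "blocktrain_invalid_state")
})

test_that("power at a lactate level interpolates between bracketing steps", {
  prof <- lactate_profile(c(175, 225, 250), c(1.4, 3.0, 4.6))
  expect_equal(po_at_lactate(prof, 4), 225 + (4 - 3) * 25 / 1.6)  # 240.625
  # exact hit returns the step power
  prof2 <- lactate_profile(c(250, 275, 300), c(2.1, 3.0, 4.0))
  expect_equal(po_at_lactate(prof2, 4), 300)
  # unreached level and level below the first step both refuse extrapolation
  expect_error(po_at_lactate(lactate_profile(c(175, 225), c(1.4, 3.1)), 4),
               class = "blocktrain_not_bracketed")
  expect_error(po_at_lactate(lactate_profile(c(175, 225), c(1.4, 3.1)), 1.0),
               class = "blocktrain_not_bracketed")
})

test_that("interpolated threshold power is monotone in the lactate level", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(4:9, 1)
      pw <- 125 + cumsum(sample(c(25, 50), n, replace = TRUE))
      la <- sort(runif(n, 0.8, 6)) # monotone convex-ish curve
      prof <- lactate_profile(pw, la)
      levels <- sort(runif(5, min(la) + 0.01, max(la)))
      pos <- vapply(levels, function(l) po_at_lactate(prof, l), numeric(1))
      expect_true(all(diff(pos) >= -1e-12))
    }
  })
})

test_that("interpolation matches the dense-grid piecewise-linear oracle", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      n <- sample(4:8, 1)
      pw <- 125 + (0:(n - 1)) * 50
      la <- cumsum(runif(n, 0.1, 1.5)) + 0.8
      prof <- lactate_profile(pw, la)
      lvl <- runif(1, la[1] + 0.05, la[n] - 0.05)
      expect_equal(po_at_lactate(prof, lvl), brute_po_at_level(pw, la, lvl),
                   tolerance = 1e-9)
    }
  })
})

test_that("noise-free synthetic profiles recover the closed-form threshold root", {
  phys <- fixed_phys(p4 = 283)
  prof <- simulate_step_test(phys, noise = no_noise(), seed = 1)
  root <- blocktrain:::po_at_lactate_true(phys, 4)
  expect_equal(root, 283)  # curve parametrized so the root is the latent P4
  est <- po_at_lactate(prof, 4)
  expect_lt(abs(est - root), 25)  # within one fine increment
  # a dense-step protocol converges toward the root
  dense <- simulate_step_test(phys, step_protocol(coarse_increment = 10,
                                                  fine_increment = 2),
                              noise = no_noise(), seed = 1)
  expect_lt(abs(po_at_lactate(dense, 4) - root), 1.5)
  # the chord of a convex curve reaches the level early: estimate below root
  expect_lte(est, root + 1e-9)
})

test_that("a flat lactate curve yields a non-terminating profile", {
  phys <- fixed_phys()
  phys$la_amp <- 1e-9
  prof <- simulate_step_test(phys, noise = no_noise(), seed = 2)
  expect_false(attr(prof, "terminated"))
  expect_error(po_at_lactate(prof, 4), class = "blocktrain_not_bracketed")
})

test_that("step-test simulation is deterministic under a fixed seed", {
  phys <- fixed_phys()
  a <- simulate_step_test(phys, seed = 9)
  b <- simulate_step_test(phys, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("fractional utilization interpolates %VO2max against power", {
  prof <- lactate_profile(c(250, 275), c(2.5, 3.4), vo2_ml_min = c(3000, 3500))
  expect_equal(fractional_utilization_at_power(prof, 4400, 260),
               100 * 3200 / 4400, tolerance = 1e-12)
  expect_equal(fractional_utilization_at_power(prof, 4400, 275),
               100 * 3500 / 4400, tolerance = 1e-12)
  # vo2max equal to the interpolated uptake gives exactly 100%
  expect_equal(fractional_utilization_at_power(prof, 3200, 260), 100,
               tolerance = 1e-12)
  expect_error(fractional_utilization_at_power(prof, 4400, 300),
               class = "blocktrain_not_bracketed")
})
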