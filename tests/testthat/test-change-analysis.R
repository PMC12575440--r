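make_long <- function(id, block, outcome, value) {
  tibble::tibble(participant_id = id, block = block, outcome = outcome,
                 value = value)
}

test_that("change scores compute per-participant deltas and percent changes", {
  pre <- make_long(c("a", "b"), "MIT", "po_4mmol_w_kg", c(4.0, 3.9))
  post <- make_long(c("a", "b"), "MIT", "po_4mmol_w_kg", c(4.2, 4.1))
  cs <- change_scores(pre, post)
  expect_equal(cs$delta, c(0.2, 0.2))
  expect_equal(cs$pct[1], 5.0, tolerance = 1e-12)
  # pct and delta stay mutually consistent
  expect_equal(cs$pct * cs$pre / 100, cs$delta, tolerance = 1e-12)
  # pre = post gives all-zero deltas
  cs0 <- change_scores(pre, pre)
  expect_true(all(cs0$delta == 0))
  # unmatched keys are excluded with a warning
  expect_warning(cs1 <- change_scores(pre, post[1, ]), "unmatched")
  expect_equal(nrow(cs1), 1)
})

test_that("Cohen's d uses the pooled SD and is antisymmetric", {
  a <- c(2, 4, 6); b <- c(0, 2, 4)   # both SD 2, means 4 and 2
  expect_equal(cohens_d(a, b), 1.0, tolerance = 1e-12)
  expect_equal(cohens_d(b, a), -1.0, tolerance = 1e-12)
  expect_equal(cohens_d(a, a), 0)
  withr::with_seed(51, {
    for (rep in 1:10) {
      x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1))
      nx <- length(x); ny <- length(y)
      sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
      expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp, tolerance = 1e-12)
    }
  })
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "blocktrain_invalid_argument")
})

test_that("effect-size labels follow the highly trained interpretation scale", {
  expect_equal(rhea_label(c(0, 0.24, 0.25, -0.34, 0.49, 0.5, 0.64, 1.0, 1.01)),
               c("trivial", "trivial", "small", "small", "small", "moderate",
                 "moderate", "moderate", "large"))
})

test_that("block comparison handles identical and contrasting changes", {
  ids <- sprintf("p%02d", 1:10)
  withr::with_seed(52, {
    pre <- rbind(make_long(ids, "MIT", "x", rnorm(10, 4, 0.4)),
                 make_long(ids, "HIT", "x", rnorm(10, 4, 0.4)))
    post <- pre
    post$value <- post$value + 0.2   # same shift in both blocks
    cs <- change_scores(pre, post)
    cmp <- compare_blocks(cs, "x")
    expect_equal(cmp$contrast, 0)
    expect_equal(cmp$p_block_time, 1)
    # a genuine MIT-only improvement shows up in the contrast
    post2 <- pre
    bump <- ifelse(post2$block == "MIT", 0.4, 0.05) + rnorm(20, 0, 0.02)
    post2$value <- post2$value + bump
    cmp2 <- compare_blocks(change_scores(pre, post2), "x")
    expect_gt(cmp2$contrast, 0.2)
    expect_lt(cmp2$p_block_time, 0.01)
    expect_gt(cmp2$cohens_d, 1)
  })
})

test_that("the adjusted contrast matches a mixed-model block-by-time estimate", {
  skip_if_not_installed("lme4")
  withr::with_seed(53, {
    n <- 16
    ids <- sprintf("p%02d", 1:n)
    base_mit <- rnorm(n, 4, 0.4); base_hit <- base_mit + rnorm(n, 0.05, 0.1)
    d_mit <- 0.18 + rnorm(n, 0, 0.15); d_hit <- 0.08 + rnorm(n, 0, 0.1)
    pre <- rbind(make_long(ids, "MIT", "x", base_mit),
                 make_long(ids, "HIT", "x", base_hit))
    post <- pre
    post$value <- post$value + c(d_mit, d_hit)
    cmp <- compare_blocks(change_scores(pre, post), "x")

    long <- rbind(
      data.frame(id = ids, block = "MIT", time = "pre", y = base_mit,
                 base = base_mit),
      data.frame(id = ids, block = "MIT", time = "post", y = base_mit + d_mit,
                 base = base_mit),
      data.frame(id = ids, block = "HIT", time = "pre", y = base_hit,
                 base = base_hit),
      data.frame(id = ids, block = "HIT", time = "post", y = base_hit + d_hit,
                 base = base_hit))
    long$block <- factor(long$block, c("HIT", "MIT"))
    long$time <- factor(long$time, c("pre", "post"))
    fit <- suppressMessages(lme4::lmer(
      y ~ block * time + scale(base, scale = FALSE) + (1 | id), data = long))
    mm <- lme4::fixef(fit)[["blockMIT:timepost"]]
    expect_equal(cmp$contrast, mm, tolerance = 0.02)
  })
})

test_that("the paired contrast keeps its nominal rejection rate and power", {
  withr::with_seed(54, {
    n <- 22
    reps <- 400
    rej_null <- 0; rej_alt <- 0
    ids <- sprintf("p%02d", 1:n)
    for (r in seq_len(reps)) {
      base <- rnorm(n, 4, 0.4)
      pre <- rbind(make_long(ids, "A", "x", base),
                   make_long(ids, "B", "x", base + rnorm(n, 0, 0.1)))
      d_null <- c(rnorm(n, 0.1, 0.15 / sqrt(2)), rnorm(n, 0.1, 0.15 / sqrt(2)))
      post <- pre; post$value <- post$value + d_null
      p0 <- compare_blocks(change_scores(pre, post), "x",
                           blocks = c("A", "B"))$p_block_time
      rej_null <- rej_null + (p0 <= 0.05)
      d_alt <- c(rnorm(n, 0.10, 0.15 / sqrt(2)), rnorm(n, 0, 0.15 / sqrt(2)))
      post2 <- pre; post2$value <- post2$value + d_alt
      p1 <- compare_blocks(change_scores(pre, post2), "x",
                           blocks = c("A", "B"))$p_block_time
      rej_alt <- rej_alt + (p1 <= 0.05)
    }
    # nominal 5% level (Monte-Carlo tolerance) and analytic paired-t power
    expect_lt(abs(rej_null / reps - 0.05), 0.03)
    pow <- power.t.test(n = n, delta = 0.10, sd = 0.15,
                        type = "one.sample")$power
    expect_lt(abs(rej_alt / reps - pow), 0.07)
  })
})

test_that("adjusted regression matches the normal-equations oracle", {
  withr::with_seed(55, {
    n <- 24
    df <- tibble::tibble(
      y = rnorm(n), t90 = runif(n, 0, 20), baseline = rnorm(n, 70, 5),
      d_body_mass = rnorm(n, 0, 0.5))
    fit <- fit_adjusted_regression(df, "y", "t90")
    X <- cbind(1, df$t90, df$baseline, df$d_body_mass)
    beta <- solve(t(X) %*% X, t(X) %*% df$y)
    expect_equal(fit$estimate, beta[2], tolerance = 1e-8)
    expect_true(fit$ci_lo < fit$estimate && fit$estimate < fit$ci_hi)
    # adjusted R2 follows its defining formula
    p <- 3
    expect_equal(fit$r2_adj, 1 - (1 - fit$r2) * (n - 1) / (n - p - 1),
                 tolerance = 1e-12)
    expect_lte(fit$r2_adj, fit$r2)
  })
})

test_that("noise-free linear data give a perfect adjusted fit", {
  df <- tibble::tibble(t90 = 1:12, baseline = rep(c(60, 70, 80), 4),
                       d_body_mass = rep(c(-0.5, 0.5), 6))
  df$y <- 0.4 * df$t90 + 0.1 * df$baseline - 0.3 * df$d_body_mass + 2
  # lm warns that the fit is essentially perfect; that is the point here
  fit <- suppressWarnings(fit_adjusted_regression(df, "y", "t90"))
  expect_equal(fit$estimate, 0.4, tolerance = 1e-10)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-10)
  expect_lt(fit$ci_hi - fit$ci_lo, 1e-8)
})

test_that("rank-deficient designs are refused with the collinear term named", {
  df <- tibble::tibble(y = rnorm(10), t90 = 1:10, baseline = 2 * (1:10),
                       d_body_mass = rnorm(10))
  expect_error(fit_adjusted_regression(df, "y", "t90"),
               class = "blocktrain_invalid_argument")
})

test_that("a built-in uptake-time slope is recovered across replicates", {
  withr::with_seed(56, {
    reps <- 100
    est <- numeric(reps)
    for (r in seq_len(reps)) {
      n <- 22
      t90 <- pmax(0, rnorm(n, 10.6, 7.7))
      baseline <- rnorm(n, 71, 6.5)
      dbm <- rnorm(n, 0.2, 0.6)
      dv <- 0.41 * t90 - 0.05 * (baseline - 71) - 0.4 * dbm + rnorm(n, -2, 2.2)
      df <- tibble::tibble(y = dv, t90 = t90, baseline = baseline,
                           d_body_mass = dbm)
      est[r] <- fit_adjusted_regression(df, "y", "t90")$estimate
    }
    expect_lt(abs(mean(est) - 0.41), 0.05)
  })
})
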