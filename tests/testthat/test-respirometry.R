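test_that("oxygen slope is exact on linear input and zero on constant input", {
  tt <- seq(0, 870, by = 5)
  cyc <- fit_o2_slope(tt, 8.0 - 0.05 * tt / 60)
  expect_equal(cyc$slope_per_min, -0.05, tolerance = 1e-12)
  expect_equal(cyc$r_squared, 1, tolerance = 1e-12)
  flat <- fit_o2_slope(tt, rep(7.2, length(tt)))
  expect_equal(flat$slope_per_min, 0)
})

test_that("noisy slope matches an independently coded least-squares oracle", {
  set.seed(42)
  for (i in 1:10) {
    tt <- seq(0, 900, by = 5)
    y <- 8 - runif(1, 0.01, 0.1) * tt / 60 + rnorm(length(tt), 0, 0.01)
    cyc <- fit_o2_slope(tt, y)
    oracle <- unname(coef(lm(y ~ tt))[2]) * 60
    expect_equal(cyc$slope_per_min, oracle, tolerance = 1e-12)
    expect_equal(cyc$r_squared, summary(lm(y ~ tt))$r.squared, tolerance = 1e-10)
  }
})

test_that("leading trim removes a contaminated mixing transient", {
  tt <- seq(0, 300, by = 5)
  y <- 8 - 0.05 * tt / 60
  y[tt < 30] <- y[tt < 30] + 0.5 # transient before the water is mixed
  raw <- fit_o2_slope(tt, y)
  trimmed <- fit_o2_slope(tt, y, trim_leading_s = 30)
  expect_gt(abs(raw$slope_per_min + 0.05), 1e-3)
  expect_equal(trimmed$slope_per_min, -0.05, tolerance = 1e-12)
})

test_that("degenerate slope segments are rejected", {
  expect_error(fit_o2_slope(c(0, 5), c(8, 7.9)), "3 points")
  expect_error(fit_o2_slope(c(0, 5, 5, 10), c(8, 7.9, 7.9, 7.8)), "increasing")
  expect_error(fit_o2_slope(seq(0, 100, 5), 8 - seq(0, 100, 5), trim_leading_s = 95), "3 points")
})

test_that("MO2 follows (Vr - Vf) times the negative slope", {
  expect_equal(compute_mo2(-0.05, Vr = 40, Vf = 2), 1.9)
  expect_equal(compute_mo2(0, Vr = 40, Vf = 2), 0)
  expect_equal(compute_mo2(-0.01, Vr = 40, Vf = 0), 0.4)
  expect_error(compute_mo2(-0.05, Vr = 40, Vf = 40), "smaller")
  expect_error(compute_mo2(-0.05, Vr = 40, Vf = -1), ">= 0")
})

test_that("blank correction interpolates linearly and clamps outside the blanks", {
  bs <- blank_series(0, 0.1, 10 * 3600, 0.3)
  expect_equal(blank_correct(2.0, 5 * 3600, bs), 1.8)
  expect_equal(blank_correct(2.0, -3600, bs), 1.9) # clamped at pre rate
  expect_equal(blank_correct(2.0, 20 * 3600, bs), 1.7) # clamped at post rate
  eq <- blank_series(0, 0.2, 3600, 0.2)
  expect_equal(blank_correct(c(1, 2, 3), c(0, 1800, 7200), eq), c(0.8, 1.8, 2.8))
  # over-correction is preserved, not clipped
  expect_lt(blank_correct(0.05, 1800, eq), 0)
})

test_that("missing blanks degrade gracefully or fail loudly", {
  one <- blank_series(0, 0.1, 10, NA)
  expect_warning(out <- blank_correct(2, 5, one), "post-trial blank missing")
  expect_equal(out, 1.9)
  expect_error(blank_series(0, NA, 10, NA), "at least one")
  expect_error(blank_series(0, 0.1, -5, 0.2), "after")
  expect_error(blank_series(0, -0.1, 10, 0.2), ">= 0")
})

test_that("SMR rule: outlier screen then mean of the lowest decile", {
  # twenty cycles 1..20: none beyond +/-2 SD, lowest decile is {1, 2}
  est <- extract_smr(1:20)
  expect_equal(est$smr, 1.5)
  expect_equal(est$n_outliers, 0)
  # all equal
  est <- extract_smr(rep(5, 12))
  expect_equal(est$smr, 5)
  expect_equal(est$n_outliers, 0)
  # nineteen fives and one spike at 50: spike excluded, SMR 5
  est <- extract_smr(c(rep(5, 19), 50))
  expect_equal(est$smr, 5)
  expect_equal(est$n_outliers, 1)
  expect_error(extract_smr(3), "at least 2")
})

test_that("SMR extraction is permutation-invariant and scale-equivariant", {
  set.seed(9)
  for (i in 1:10) {
    x <- rlnorm(25, 0, 0.4)
    base <- extract_smr(x)$smr
    expect_equal(extract_smr(sample(x))$smr, base)
    c0 <- runif(1, 0.5, 4)
    expect_equal(extract_smr(c0 * x)$smr, c0 * base, tolerance = 1e-12)
  }
})

test_that("subset-first outlier ordering is available and differs when it should", {
  x <- c(rep(5, 19), 50)
  g <- extract_smr(x, outlier_order = "global")
  s <- extract_smr(x, outlier_order = "subset")
  expect_equal(g$smr, 5)
  # subset mode screens within the lowest decile only (both fives here)
  expect_equal(s$smr, 5)
  expect_equal(s$n_outliers, 0)
})

test_that("aerobic scopes and protocol flags are derived correctly", {
  est <- summarize_metabolism("f", smr = 1, mmr = 3)
  expect_equal(est$aerobic_scope, 2)
  expect_equal(est$factorial_scope, 3)
  expect_equal(est$flags, "")
  eq <- summarize_metabolism("f", smr = 2, mmr = 2)
  expect_equal(eq$aerobic_scope, 0)
  expect_equal(eq$factorial_scope, 1)
  expect_match(eq$flags, "chase_underestimate")
  ok <- summarize_metabolism("f", smr = 1.0, rmr = 1.35, mmr = 1.7)
  expect_equal(ok$factorial_scope, 1.7)
  expect_equal(ok$flags, "")
  neg <- summarize_metabolism("f", smr = -0.1, mmr = 1)
  expect_match(neg$flags, "nonpositive_smr")
  expect_true(is.na(neg$factorial_scope))
})

test_that("noise-free traces return the generator's rates to 1e-9", {
  cfg <- identity_cohort_config(seed = 2)
  co <- generate_cohort(cfg)
  fish <- co[3, ]
  tr <- generate_trial_traces(fish, clean_trace_config(), seed = 4)
  est <- extract_metabolism(tr, co)
  expect_equal(est$smr, fish$true_smr, tolerance = 1e-9)
  expect_equal(est$rmr, fish$true_rmr, tolerance = 1e-9)
  expect_equal(est$mmr, fish$true_mmr, tolerance = 1e-9)
})

test_that("a truly linear background drift is corrected exactly", {
  cfg <- identity_cohort_config(seed = 2)
  co <- generate_cohort(cfg)
  fish <- co[1, ]
  tc <- trace_config(
    sensor_noise_sd = 0, burst_rate_per_h = 0,
    blank_rate_start = 0.05, blank_rate_end = 0.30, smr_duration_h = 2
  )
  est <- extract_metabolism(generate_trial_traces(fish, tc, seed = 6), co)
  expect_equal(est$smr, fish$true_smr, tolerance = 1e-9)
  expect_equal(est$rmr, fish$true_rmr, tolerance = 1e-9)
  expect_equal(est$mmr, fish$true_mmr, tolerance = 1e-9)
})

test_that("default-noise overnight runs recover SMR within a few percent", {
  co <- generate_cohort(cohort_config(seed = 21))
  errs <- vapply(1:5, function(i) {
    fish <- co[i, ]
    tr <- generate_trial_traces(fish, trace_config(smr_duration_h = 6), seed = 30 + i)
    est <- extract_metabolism(tr, co)
    abs(est$smr - fish$true_smr) / fish$true_smr
  }, 0)
  expect_lt(median(errs), 0.05)
})

test_that("trace extraction validates its input schema", {
  co <- generate_cohort(small_cohort_config(seed = 1))
  tr <- generate_trial_traces(co[1, ], clean_trace_config(), seed = 1)
  expect_error(extract_metabolism(tr[, -6], co), "missing columns")
  expect_error(extract_metabolism(tr, co[, c("fish_id", "mass_mg")]), "volume_ml")
  no_blank <- tr[tr$kind != "blank", ]
  expect_error(extract_metabolism(no_blank, co), "blank")
})
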