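test_that("sample_cohort honors counts, labels and invariant ranges", {
  co <- sample_cohort(26, 15, seed = 1)
  g <- vapply(co$subjects, `[[`, "", "gender")
  expect_length(co$subjects, 41)
  expect_equal(sum(g == "M"), 26)
  expect_equal(sum(g == "F"), 15)
  expect_equal(co$sessions_per_subject, 6)
  expect_equal(co$session_duration, 60)
  expect_equal(co$fps, 24)

  for (p in co$subjects) {
    expect_gte(p$gait_cycle_period, 0.8)
    expect_lte(p$gait_cycle_period, 2.4)
    expect_gt(p$hip_sway_amp, 0)
    expect_gt(p$shoulder_sway_amp, 0)
    expect_gt(p$height, 0)
    expect_gt(p$stride_length, 0)
  }

  # degenerate single-subject cohort
  one <- sample_cohort(0, 1, seed = 7)
  expect_length(one$subjects, 1)
  expect_equal(one$subjects[[1]]$gender, "F")

  expect_error(sample_cohort(0, 0), "invalid cohort")
  expect_error(sample_cohort(-1, 5), "invalid cohort")
})

test_that("cohort sampling is reproducible and plants the sway-ratio effect", {
  a <- sample_cohort(8, 8, seed = 42)
  b <- sample_cohort(8, 8, seed = 42)
  expect_identical(a, b)

  # large-sample check against the configured generating means
  cfg <- effect_config()
  co <- sample_cohort(1000, 1000, seed = 3, config = cfg)
  g <- vapply(co$subjects, `[[`, "", "gender")
  ratio <- vapply(co$subjects, function(p) p$shoulder_sway_amp / p$hip_sway_amp, 0)
  m_mean <- mean(ratio[g == "M"])
  f_mean <- mean(ratio[g == "F"])
  expect_gt(m_mean, f_mean)
  # empirical means within 3 SE of the configured truncated-normal means
  se <- cfg$sway_ratio$sd / sqrt(1000)
  expect_lt(abs(m_mean - cfg$sway_ratio$male), 3 * se + 0.01)
  expect_lt(abs(f_mean - cfg$sway_ratio$female), 3 * se + 0.01)
})

test_that("generate_walk frame count, determinism and treadmill convention", {
  p <- quiet_params(noise_sd = 0.005)
  w <- generate_walk(p, duration = 60, fps = 24, seed = 5)
  expect_equal(n_frames(w), 1440)
  expect_equal(dim(w$positions), c(1440, 20, 3))

  w2 <- generate_walk(p, duration = 60, fps = 24, seed = 5)
  expect_identical(w$positions, w2$positions)
  w3 <- generate_walk(p, duration = 60, fps = 24, seed = 6)
  expect_false(identical(w$positions, w3$positions))

  # treadmill convention: no anterior pelvis drift at zero noise
  q <- quiet_params()
  wq <- generate_walk(q, duration = 20, fps = 24, seed = 1)
  z <- wq$positions[, "pelvis", "z"]
  slope <- coef(lm(z ~ seq_along(z)))[2]
  expect_lt(abs(slope), 1e-9)

  expect_error(generate_walk(p, duration = 0), "positive")
  expect_error(generate_walk(p, fps = -1), "positive")
})

test_that("zero-amplitude parameters produce a static skeleton", {
  p <- gait_params("S0", "M",
    stride_length = 0, shoulder_sway_amp = 0, hip_sway_amp = 0,
    vertical_bounce_amp = 0, arm_swing_amp = 0, knee_flexion_max = 0,
    noise_sd = 0
  )
  w <- generate_walk(p, duration = 2, fps = 24, seed = 1)
  first <- w$positions[1, , ]
  for (i in seq_len(n_frames(w))) {
    expect_equal(w$positions[i, , ], first, tolerance = 1e-12)
  }
})

test_that("generated gait is periodic at the configured stride period", {
  p <- quiet_params(gait_cycle_period = 1.6)
  w <- generate_walk(p, duration = 20, fps = 24, seed = 1)
  x <- w$positions[, "ankle_l", "x"]
  ac <- acf(x, lag.max = 60, plot = FALSE)$acf[, 1, 1]
  # strongest autocorrelation peak beyond half a period at lag 38-39 frames
  cand <- 25:60
  peak_lag <- cand[which.max(ac[cand + 1])]
  expect_true(peak_lag %in% 38:39)
})

test_that("ground_truth_metrics closed forms", {
  p <- quiet_params(gait_cycle_period = 1.6, stride_length = 1.2, duty_factor = 0.62)
  gt <- ground_truth_metrics(p)
  expect_length(gt, 12)
  expect_equal(gt[["cadence"]], 75) # 120 / 1.6
  expect_equal(gt[["speed"]], 0.75) # 1.2 / 1.6
  expect_equal(gt[["stride_length"]], 1.2)
  expect_equal(gt[["stance_swing_ratio_l"]], 0.62 / 0.38)
  expect_equal(gt[["single_support"]] + gt[["double_support"]], 1)
})

test_that("gait_params rejects invariant violations", {
  expect_error(gait_params("x", "M", gait_cycle_period = 0.5), "0.8")
  expect_error(gait_params("x", "M", gait_cycle_period = 3), "0.8")
  expect_error(gait_params("x", "M", height = -1), "positive")
  expect_error(gait_params("x", "M", hip_sway_amp = -0.1), "non-negative")
  expect_error(gait_params("x", "Q"), "arg")
})
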