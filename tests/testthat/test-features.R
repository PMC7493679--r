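test_that("static_summary matches closed forms and dimensionality", {
  # a 60-dimensional window gives a 240-dimensional summary
  win <- matrix(rnorm(10 * 60), 10, 60)
  expect_length(static_summary(win), 240L)

  const <- matrix(3.5, 8, 2)
  expect_equal(unname(static_summary(const)), rep(c(3.5, 3.5, 3.5, 0), 2))

  v <- matrix(c(1, 2, 3), 3, 1)
  s <- unname(static_summary(v))
  expect_equal(s[1:3], c(1, 3, 2))
  expect_equal(s[4], sqrt(2 / 3), tolerance = 1e-12) # population SD

  expect_error(static_summary(matrix(0, 0, 3)), "non-empty")
})

test_that("static_summary is invariant to frame order; LSTM output is not", {
  set.seed(8)
  win <- matrix(rnorm(30 * 6), 30, 6)
  shuf <- win[sample(30), ]
  expect_equal(static_summary(shuf), static_summary(win))

  b <- blob_windows(10, frames = 12, d = 6)
  hp <- lstm_hyperparams(hidden_size = 6, epochs = 3, batch_size = 10, seed = 1)
  m <- train_lstm(b$windows, b$labels, hp)
  # structured (non-iid) window so order carries information
  w <- matrix(sin(outer(1:12, 1:6) / 3), 12, 6)
  p1 <- predict(m, w)
  changed <- vapply(1:20, function(i) {
    set.seed(i)
    p2 <- predict(m, w[sample(12), , drop = FALSE])
    abs(p2[[2]] - p1[[2]]) > 1e-8
  }, logical(1))
  expect_gt(mean(changed), 0.9)
})

test_that("gait events: counts, alternation and failure on static input", {
  p <- quiet_params(gait_cycle_period = 1.6)
  w <- generate_walk(p, duration = 10, fps = 24, seed = 1)
  ev <- detect_gait_events(w)
  expect_equal(ev$cycle_period, 1.6, tolerance = 0.05)
  for (side in c("l", "r")) {
    hs <- ev[[side]]$heel_strikes
    to <- ev[[side]]$toe_offs
    # ~6 strides in 10 s at 1.6 s/stride, boundary effects allowed
    expect_gte(length(hs), 5)
    expect_lte(length(hs), 7)
    # alternation: HS -> TO -> HS per foot
    expect_length(to, length(hs) - 1L)
    expect_true(all(to > hs[-length(hs)] & to < hs[-1]))
    expect_true(all(diff(hs) > 0))
  }

  static <- gait_params("S0", "M",
    stride_length = 0, shoulder_sway_amp = 0, hip_sway_amp = 0,
    vertical_bounce_amp = 0, arm_swing_amp = 0, knee_flexion_max = 0,
    noise_sd = 0
  )
  ws <- generate_walk(static, duration = 5, fps = 24, seed = 1)
  expect_error(detect_gait_events(ws), "no gait detected")
})

test_that("clinical metrics recover generator ground truth at zero noise", {
  p <- quiet_params(gait_cycle_period = 1.6, stride_length = 1.2)
  w <- generate_walk(p, duration = 15, fps = 24, seed = 1)
  ev <- detect_gait_events(w)
  m <- clinical_metrics(w, ev)
  expect_length(m, 12)
  gt <- ground_truth_metrics(p)
  expect_equal(names(m), names(gt))

  expect_equal(m[["cadence"]], 75, tolerance = 4 / 75)
  expect_equal(m[["speed"]], 0.75, tolerance = 0.05 / 0.75)
  expect_equal(m[["stride_length"]], 1.2, tolerance = 0.05)

  # symmetric generator: left/right stance:swing ratios agree within 2%
  expect_equal(m[["stance_swing_ratio_l"]], m[["stance_swing_ratio_r"]],
    tolerance = 0.02
  )
  # support fractions are fractions and internally consistent
  expect_true(m[["single_support"]] >= 0 && m[["single_support"]] <= 1)
  expect_true(m[["double_support"]] >= 0 && m[["double_support"]] <= 1)
  expect_equal(m[["single_support"]] + m[["double_support"]], 1, tolerance = 0.05)
})

test_that("knee-flexion metrics vanish for a stiff-kneed walker", {
  p <- quiet_params(knee_flexion_max = 0)
  w <- generate_walk(p, duration = 10, fps = 24, seed = 1)
  m <- clinical_metrics(w, detect_gait_events(w))
  for (nm in c(
    "knee_flex_stance_l", "knee_flex_stance_r",
    "knee_flex_swing_l", "knee_flex_swing_r"
  )) {
    expect_lt(abs(m[[nm]]), 1)
  }
})

test_that("event detection is robust to sensor-scale jitter", {
  # event counts unchanged vs zero noise in >= 95% of sessions at 5 mm jitter
  n_match <- 0
  n_tot <- 20
  for (i in seq_len(n_tot)) {
    p0 <- quiet_params()
    pn <- quiet_params(noise_sd = 0.005)
    w0 <- generate_walk(p0, duration = 10, fps = 24, seed = i)
    wn <- generate_walk(pn, duration = 10, fps = 24, seed = i)
    c0 <- length(detect_gait_events(w0)$l$heel_strikes)
    cn <- length(detect_gait_events(wn)$l$heel_strikes)
    n_match <- n_match + (c0 == cn)
  }
  expect_gte(n_match / n_tot, 0.95)
})
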