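make_seq <- function(pos_fn, n = 48, fps = 24) {
  pos <- array(0, dim = c(n, 20, 3))
  for (j in 1:20) {
    for (a in 1:3) pos[, j, a] <- pos_fn(j, a, (seq_len(n) - 1) / fps)
  }
  skeleton_sequence((seq_len(n) - 1) / fps, pos, fps = fps)
}

test_that("height_normalize fixes extent, centers pelvis, preserves ratios", {
  p <- quiet_params(height = 2.0)
  w <- generate_walk(p, duration = 5, fps = 24, seed = 1)
  hn <- height_normalize(w)
  extent <- median(hn$positions[, "head", "y"] -
    pmin(hn$positions[, "foot_l", "y"], hn$positions[, "foot_r", "y"]))
  expect_equal(extent, 1, tolerance = 1e-9)
  expect_equal(mean(hn$positions[, "pelvis", "x"]), 0, tolerance = 1e-9)

  # two walkers of different stature end at identical extents: height cue gone
  p2 <- quiet_params(height = 1.3)
  hn2 <- height_normalize(generate_walk(p2, duration = 5, fps = 24, seed = 1))
  extent2 <- median(hn2$positions[, "head", "y"] -
    pmin(hn2$positions[, "foot_l", "y"], hn2$positions[, "foot_r", "y"]))
  expect_equal(extent, extent2, tolerance = 1e-9)

  # sway ratio survives the uniform rescale
  ratio_of <- function(s) {
    sd(s$positions[, "neck", "x"]) / sd(s$positions[, "pelvis", "x"])
  }
  expect_equal(ratio_of(hn), ratio_of(w), tolerance = 1e-9)

  # idempotent
  hn_twice <- height_normalize(hn)
  expect_equal(hn_twice$positions, hn$positions, tolerance = 1e-9)
})

test_that("moving average preserves constants and affine ramps, spreads impulses", {
  const <- make_seq(function(j, a, t) j + a)
  smc <- smooth_moving_average(const, 5)
  expect_equal(smc$positions, const$positions, tolerance = 1e-12)

  ramp <- make_seq(function(j, a, t) 2 * t + j)
  smr <- smooth_moving_average(ramp, 5)
  interior <- 3:(n_frames(ramp) - 2)
  expect_equal(smr$positions[interior, , ], ramp$positions[interior, , ], tolerance = 1e-12)

  imp <- make_seq(function(j, a, t) ifelse(seq_along(t) == 20, 1, 0))
  smi <- smooth_moving_average(imp, 5)
  expect_equal(smi$positions[18:22, 1, 1], rep(0.2, 5), tolerance = 1e-12)
  expect_equal(smi$positions[c(17, 23), 1, 1], c(0, 0), tolerance = 1e-12)

  expect_error(smooth_moving_average(const, 0), "window")
})

test_that("differentiate matches analytic derivatives", {
  const <- make_seq(function(j, a, t) 7)
  expect_true(all(differentiate(const, 24)$positions == 0))

  lin <- make_seq(function(j, a, t) 1.5 * t)
  v <- differentiate(lin, 24)
  expect_equal(as.vector(v$positions), rep(1.5, length(v$positions)), tolerance = 1e-9)
  expect_equal(n_frames(v), n_frames(lin)) # length-preserving

  # sinusoid: velocity amplitude ~ 2*pi*f*A within the discretization bound
  A <- 0.5
  f <- 1.25
  fps <- 24
  sine <- make_seq(function(j, a, t) A * sin(2 * pi * f * t), n = 240, fps = fps)
  v <- differentiate(sine, fps)
  amp <- max(abs(v$positions[, 1, 1]))
  bound <- (2 * pi * f / fps)^2 / 6 + 1e-9
  expect_lt(abs(amp - 2 * pi * f * A) / (2 * pi * f * A), bound)

  one <- make_seq(function(j, a, t) t, n = 1)
  expect_error(differentiate(one, 24), "2 frames")
})

test_that("differentiate inverts cumulative summation", {
  set.seed(4)
  n <- 100
  fps <- 24
  steps <- rnorm(n)
  pos <- array(0, dim = c(n, 20, 3))
  pos[, 1, 1] <- cumsum(steps) / fps
  s <- skeleton_sequence((seq_len(n) - 1) / fps, pos, fps = fps)
  v <- differentiate(s, fps)
  expect_equal(v$positions[1:(n - 1), 1, 1], steps[2:n], tolerance = 1e-9)
})

test_that("coronal projection drops z, is idempotent, keeps x and y", {
  p <- quiet_params()
  w <- generate_walk(p, duration = 2, fps = 24, seed = 1)
  pr <- project_coronal(w)
  expect_equal(dim(pr$positions), c(n_frames(w), 20, 2))
  expect_equal(ncol(as_frame_matrix(pr)), 40L)
  expect_equal(pr$positions[, , "x"], w$positions[, , "x"])
  expect_equal(pr$positions[, , "y"], w$positions[, , "y"])
  pr2 <- project_coronal(pr)
  expect_identical(pr2$positions, pr$positions)
})

test_that("window_split arithmetic and degenerate cases", {
  mat <- matrix(rnorm(1440 * 4), 1440, 4)
  expect_length(window_split(mat, window_spec(1)), 144L)
  expect_length(window_split(mat, window_spec(10)), 14L)
  w <- window_split(mat, window_spec(3))
  expect_true(all(vapply(w, nrow, 0L) == 30L))
  expect_warning(out <- window_split(matrix(0, 9, 4), window_spec(1)), "shorter")
  expect_length(out, 0L)
  expect_error(window_spec(11), "1..10")
  expect_equal(window_spec(4)$n_frames, 40L)
})

test_that("scaler: z-score then min-max from training data only, no clipping", {
  set.seed(2)
  x <- matrix(rnorm(200, 5, 3), 50, 4)
  st <- fit_scaler(x)
  z <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-12)

  scaled <- apply_scaler(st, x)
  expect_equal(unname(apply(scaled, 2, min)), rep(-1, 4), tolerance = 1e-12)
  expect_equal(unname(apply(scaled, 2, max)), rep(1, 4), tolerance = 1e-12)

  # train max maps to exactly +1; out-of-range test values are not clipped
  test_pt <- matrix(apply(x, 2, max), 1)
  expect_equal(unname(apply_scaler(st, test_pt)[1, ]), rep(1, 4), tolerance = 1e-12)
  big <- matrix(apply(x, 2, max) + 10, 1)
  expect_true(all(apply_scaler(st, big) > 1))

  # constant column maps to 0 with a warning
  xc <- cbind(x, 3)
  expect_warning(stc <- fit_scaler(xc), "zero-variance")
  expect_equal(unname(apply_scaler(stc, xc)[, 5]), rep(0, 50))
})

test_that("no preprocessing transform reads labels", {
  # corrupting labels leaves every fitted statistic identical
  ds <- tiny_dataset(2, 2, sessions = 1, duration = 10)
  mats <- lapply(ds, function(r) representation_matrix_for_test(r$sequence))
  x <- do.call(rbind, mats)
  st1 <- fit_scaler(x)
  # "labels" live only in metadata; shuffle them and refit
  ds2 <- ds
  for (i in seq_along(ds2)) ds2[[i]]$gender <- sample(c("M", "F"), 1)
  mats2 <- lapply(ds2, function(r) representation_matrix_for_test(r$sequence))
  st2 <- fit_scaler(do.call(rbind, mats2))
  expect_identical(st1, st2)
})
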