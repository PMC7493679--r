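test_that("LSTM parameter count matches the closed-form gate arithmetic", {
  p <- gaitlab:::lstm_init(60, 128, 0.1, 1)
  # 4 * (H * (D + H) + H) recurrent weights + 2H + 2 head weights
  expect_equal(lstm_n_parameters(p), 4 * (128 * (60 + 128) + 128) + 2 * 128 + 2)
  expect_equal(lstm_n_parameters(p), 97026L)
  p2 <- gaitlab:::lstm_init(40, 16, 0.1, 1)
  expect_equal(lstm_n_parameters(p2), 4 * (16 * (40 + 16) + 16) + 2 * 16 + 2)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(1)
  D <- 3
  H <- 4
  Tn <- 5
  B <- 2
  p <- gaitlab:::lstm_init(D, H, 0.3, 42)
  X <- array(rnorm(Tn * D * B), dim = c(Tn, D, B))
  Y <- matrix(c(1, 0, 0, 1), 2, B)
  loss_fn <- function(p) {
    fwd <- gaitlab:::lstm_forward(p, X)
    -mean(colSums(Y * log(fwd$probs)))
  }
  fwd <- gaitlab:::lstm_forward(p, X, keep_cache = TRUE)
  gr <- gaitlab:::lstm_backward(p, X, Y, fwd)
  eps <- 1e-6
  for (nm in c("W", "b", "Wy", "by")) {
    idx <- sample(length(p[[nm]]), min(10, length(p[[nm]])))
    for (i in idx) {
      p_hi <- p
      p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p
      p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      g_num <- (loss_fn(p_hi) - loss_fn(p_lo)) / (2 * eps)
      expect_equal(gr[[nm]][i], g_num, tolerance = 1e-5)
    }
  }
})

test_that("LSTM fits a separable task and its loss decreases", {
  b <- blob_windows(25, frames = 10, d = 4)
  hp <- lstm_hyperparams(hidden_size = 8, epochs = 30, batch_size = 16, seed = 3)
  m <- train_lstm(b$windows, b$labels, hp)
  pr <- predict(m, b$windows)
  expect_equal(mean(pr$label == b$labels), 1)
  expect_lt(m$loss_history[hp$epochs], m$loss_history[1])
  # probabilities are a simplex
  expect_equal(unname(rowSums(as.matrix(pr[, m$levels]))), rep(1, length(b$windows)),
    tolerance = 1e-12
  )
})

test_that("LSTM training is deterministic in (data, hp, seed) and round-trips", {
  b <- blob_windows(10, frames = 8, d = 3)
  hp <- lstm_hyperparams(hidden_size = 6, epochs = 5, batch_size = 8, seed = 7)
  m1 <- train_lstm(b$windows, b$labels, hp)
  m2 <- train_lstm(b$windows, b$labels, hp)
  expect_identical(m1$params, m2$params)
  hp2 <- hp
  hp2$seed <- 8L
  m3 <- train_lstm(b$windows, b$labels, hp2)
  expect_false(identical(m1$params, m3$params))

  # save -> load -> predict is bit-exact
  path <- tempfile(fileext = ".rds")
  saveRDS(m1, path)
  m1b <- readRDS(path)
  w <- b$windows[1:4]
  expect_identical(predict(m1, w), predict(m1b, w))
  unlink(path)
})

test_that("LSTM input contracts: ragged windows and shape mismatches", {
  b <- blob_windows(5, frames = 8, d = 3)
  bad <- b$windows
  bad[[2]] <- bad[[2]][1:5, ]
  expect_error(train_lstm(bad, b$labels), "ragged")
  expect_error(train_lstm(b$windows, rep("A", 10)), "binary")

  hp <- lstm_hyperparams(hidden_size = 4, epochs = 2, batch_size = 5, seed = 1)
  m <- train_lstm(b$windows, b$labels, hp)
  expect_error(predict(m, matrix(0, 8, 4)), "8 x 3")
  expect_error(predict(m, matrix(0, 5, 3)), "8 x 3")
})

test_that("linear SVM separates blobs; RBF solves XOR where linear cannot", {
  set.seed(5)
  n <- 60
  x <- rbind(
    matrix(rnorm(n * 2, 2), ncol = 2),
    matrix(rnorm(n * 2, -2), ncol = 2)
  )
  y <- rep(c("M", "F"), each = n)
  m <- train_static(x, y, static_model_spec("svm_linear", seed = 1))
  xt <- rbind(
    matrix(rnorm(40, 2), ncol = 2),
    matrix(rnorm(40, -2), ncol = 2)
  )
  yt <- rep(c("M", "F"), each = 20)
  expect_equal(mean(predict(m, xt)$label == yt), 1)

  # XOR arrangement
  centers <- matrix(c(2, 2, -2, -2, 2, -2, -2, 2), 4, 2, byrow = TRUE)
  make_xor <- function(n, sd = 0.5, seed = 1) {
    set.seed(seed)
    x <- do.call(rbind, lapply(1:4, function(i) {
      cbind(rnorm(n, centers[i, 1], sd), rnorm(i * 0 + n, centers[i, 2], sd))
    }))
    list(x = x, y = rep(c("A", "A", "B", "B"), each = n))
  }
  tr <- make_xor(40, seed = 2)
  te <- make_xor(25, seed = 3)
  lin <- train_static(tr$x, tr$y, static_model_spec("svm_linear", seed = 1))
  # a linear margin can never resolve XOR: at most 3 of the 4 blobs
  acc_lin <- mean(predict(lin, te$x)$label == te$y)
  expect_lte(acc_lin, 0.8)
  rbf <- train_static(tr$x, tr$y, static_model_spec("svm_rbf", seed = 1))
  acc_rbf <- mean(predict(rbf, te$x)$label == te$y)
  expect_gt(acc_rbf, 0.9)
  expect_gt(acc_rbf - acc_lin, 0.15)
})

test_that("forest uses 10 trees with majority vote and is seed-deterministic", {
  set.seed(9)
  x <- rbind(
    matrix(rnorm(100, 1.5), ncol = 2),
    matrix(rnorm(100, -1.5), ncol = 2)
  )
  y <- rep(c("M", "F"), each = 50)
  m <- train_static(x, y, static_model_spec("rdf", seed = 4))
  expect_equal(m$fit$ntree, 10)
  pr <- predict(m, x)
  # vote fractions are multiples of 1/10 and the majority side wins
  probs <- as.matrix(pr[, m$levels])
  expect_true(all(abs(probs * 10 - round(probs * 10)) < 1e-9))
  maj <- m$levels[max.col(probs, ties.method = "first")]
  expect_equal(pr$label, maj)

  m2 <- train_static(x, y, static_model_spec("rdf", seed = 4))
  expect_identical(predict(m2, x), pr)

  expect_error(train_static(x, rep("M", 100)), "two classes")
})

test_that("static models are invariant to frame order inside a window", {
  set.seed(11)
  wins <- lapply(1:30, function(i) matrix(rnorm(20 * 5), 20, 5))
  labs <- rep(c("A", "B"), 15)
  feats <- t(vapply(wins, static_summary, numeric(20)))
  m <- train_static(feats, labs, static_model_spec("svm_rbf", seed = 2))
  shuffled <- t(vapply(wins, function(w) static_summary(w[sample(20), ]), numeric(20)))
  expect_equal(predict(m, shuffled), predict(m, feats), tolerance = 1e-12)
})
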