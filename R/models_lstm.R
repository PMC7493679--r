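#' LSTM hyper-parameters
#'
#' Defaults follow the benchmark's training regime: a single standard LSTM
#' cell with 128 hidden units, zero-mean Gaussian weight initialization,
#' a ReLU on the final hidden state feeding an affine layer with 2 logits,
#' softmax cross-entropy loss, and Adam with learning rate 0.001 on
#' mini-batches of 50 for 100 epochs.
#'
#' @param hidden_size Hidden state width (default 128).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 50).
#' @param epochs Training epochs (default 100).
#' @param init_sd SD of the Gaussian weight initialization (default 0.1).
#' @param seed Integer seed controlling initialization and batch order.
#' @return List of class `lstm_hyperparams`.
#' @export
lstm_hyperparams <- function(hidden_size = 128, learning_rate = 0.001,
                             batch_size = 50, epochs = 100, init_sd = 0.1,
                             seed = 1) {
  structure(
    list(
      hidden_size = as.integer(hidden_size), learning_rate = learning_rate,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      init_sd = init_sd, seed = as.integer(seed)
    ),
    class = "lstm_hyperparams"
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Gate block layout in the 4H x (D+H) weight matrix: input, forget,
# candidate, output.
lstm_init <- function(input_size, hidden_size, init_sd, seed) {
  with_seed(seed, {
    d <- input_size
    h <- hidden_size
    W <- matrix(rnorm(4 * h * (d + h), 0, init_sd), nrow = 4 * h)
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1 # forget-gate bias init
    Wy <- matrix(rnorm(2 * h, 0, init_sd), nrow = 2)
    by <- rep(0, 2)
    list(W = W, b = b, Wy = Wy, by = by, D = d, H = h)
  })
}

#' Number of trainable parameters of an LSTM classifier
#'
#' Closed form: the recurrent block has `4 * (H * (D + H) + H)` weights and
#' biases (four gates over the concatenated input and hidden state), and
#' the affine head `2 * H + 2`.
#'
#' @param model A `gait_lstm` or a bare parameter list.
#' @return Integer parameter count.
#' @export
lstm_n_parameters <- function(model) {
  p <- if (inherits(model, "gait_lstm")) model$params else model
  length(p$W) + length(p$b) + length(p$Wy) + length(p$by)
}

# Forward pass over a batch. X: T x D x B array. Returns logits (2 x B),
# probabilities, and (optionally) the caches needed for BPTT.
lstm_forward <- function(p, X, keep_cache = FALSE) {
  Tn <- dim(X)[1]
  B <- dim(X)[3]
  H <- p$H
  h <- matrix(0, H, B)
  cst <- matrix(0, H, B)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    a <- rbind(matrix(X[t, , ], nrow = p$D), h) # (D+H) x B
    z <- p$W %*% a + p$b
    i <- sigmoid(z[1:H, , drop = FALSE])
    f <- sigmoid(z[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- sigmoid(z[(3 * H + 1):(4 * H), , drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h <- o * tc
    if (keep_cache) cache[[t]] <- list(a = a, i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc)
  }
  r <- pmax(h, 0) # ReLU on the final hidden state
  logits <- p$Wy %*% r + p$by
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  list(logits = logits, probs = probs, h_T = h, r = r, cache = cache)
}

# Backward pass: gradients of mean cross-entropy over the batch.
lstm_backward <- function(p, X, Y, fwd) {
  Tn <- dim(X)[1]
  B <- dim(X)[3]
  H <- p$H
  dlogits <- (fwd$probs - Y) / B
  dWy <- dlogits %*% t(fwd$r)
  dby <- rowSums(dlogits)
  dr <- t(p$Wy) %*% dlogits
  dh <- dr * (fwd$h_T > 0)
  dc <- matrix(0, H, B)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  db <- rep(0, length(p$b))
  for (t in rev(seq_len(Tn))) {
    cc <- fwd$cache[[t]]
    do <- dh * cc$tc
    dcs <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dcs * cc$g
    dg <- dcs * cc$i
    df <- dcs * cc$c_prev
    dc <- dcs * cc$f
    dz <- rbind(
      di * cc$i * (1 - cc$i),
      df * cc$f * (1 - cc$f),
      dg * (1 - cc$g^2),
      do * cc$o * (1 - cc$o)
    )
    dW <- dW + dz %*% t(cc$a)
    db <- db + rowSums(dz)
    da <- crossprod(p$W, dz)
    dh <- da[(p$D + 1):(p$D + H), , drop = FALSE]
  }
  list(W = dW, b = db, Wy = dWy, by = dby)
}

windows_to_array <- function(windows) {
  Tn <- nrow(windows[[1]])
  D <- ncol(windows[[1]])
  X <- array(0, dim = c(Tn, D, length(windows)))
  for (i in seq_along(windows)) X[, , i] <- windows[[i]]
  X
}

#' Train the biomimetic LSTM sequence classifier
#'
#' Trains a single-layer standard LSTM cell (input, forget and output
#' gates, tanh candidate; no peepholes; forget-gate bias initialized to 1)
#' on fixed-length gait windows by full backpropagation through time, with
#' softmax cross-entropy loss and Adam. The final hidden state is ReLU
#' activated and fed to an affine layer producing 2 logits. Deterministic
#' given `(data, hp)`.
#'
#' @param windows List of `frames x D` numeric matrices, all of identical
#'   shape (D is 60 for 3D input, 40 for coronal input).
#' @param labels Vector of binary class labels, one per window.
#' @param hp An [lstm_hyperparams()] object.
#' @param scaler Optional frozen `scaler_stats` to store with the model.
#' @return A `gait_lstm` model (also class `trained_model`) with the fitted
#'   parameters, class levels, per-epoch training loss, and a training
#'   manifest recording the input shape.
#' @export
train_lstm <- function(windows, labels, hp = lstm_hyperparams(), scaler = NULL) {
  if (!length(windows)) stop("no training windows", call. = FALSE)
  dims <- vapply(windows, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("ragged window shapes: all windows must be frames x D of identical shape",
      call. = FALSE
    )
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must be binary (two classes present)", call. = FALSE)
  y <- match(labels, lev)
  Tn <- dims[1, 1]
  D <- dims[2, 1]
  X <- windows_to_array(windows)
  N <- length(windows)
  Y_full <- matrix(0, 2, N)
  Y_full[cbind(y, seq_len(N))] <- 1

  p <- lstm_init(D, hp$hidden_size, hp$init_sd, hp$seed)
  adam <- lapply(p[c("W", "b", "Wy", "by")], function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  step <- 0
  losses <- numeric(hp$epochs)

  order_seeds <- with_seed(hp$seed + 1L, sample.int(1e9, hp$epochs))
  for (ep in seq_len(hp$epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(N))
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, N, by = hp$batch_size)) {
      idx <- ord[start:min(start + hp$batch_size - 1L, N)]
      Xb <- X[, , idx, drop = FALSE]
      Yb <- Y_full[, idx, drop = FALSE]
      fwd <- lstm_forward(p, Xb, keep_cache = TRUE)
      ep_loss <- ep_loss + -mean(colSums(Yb * log(pmax(fwd$probs, 1e-12))))
      nb <- nb + 1
      gr <- lstm_backward(p, Xb, Yb, fwd)
      step <- step + 1
      for (nm in names(gr)) {
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * gr[[nm]]
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * gr[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - beta1^step)
        vhat <- adam[[nm]]$v / (1 - beta2^step)
        p[[nm]] <- p[[nm]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    losses[ep] <- ep_loss / nb
  }

  structure(
    list(
      family = "lstm", params = p, levels = lev, hp = hp, scaler = scaler,
      loss_history = losses,
      manifest = list(n_frames = Tn, input_size = D, n_train = N, seed = hp$seed)
    ),
    class = c("gait_lstm", "trained_model")
  )
}

#' Predict gender labels from gait windows
#'
#' @param object A `gait_lstm` model.
#' @param windows A single `frames x D` matrix or a list of them; shapes
#'   must match the training manifest.
#' @param ... Unused.
#' @return Tibble with one row per window: `label` and the two class
#'   probability columns (softmax over the logits; the most probable class
#'   is the label). Deterministic.
#' @export
predict.gait_lstm <- function(object, windows, ...) {
  if (is.matrix(windows)) windows <- list(windows)
  man <- object$manifest
  dims <- vapply(windows, dim, integer(2))
  if (any(dims[1, ] != man$n_frames) || any(dims[2, ] != man$input_size)) {
    stop(sprintf(
      "window shape mismatch: model expects %d x %d frames x features",
      man$n_frames, man$input_size
    ), call. = FALSE)
  }
  X <- windows_to_array(windows)
  probs <- t(lstm_forward(object$params, X)$probs)
  colnames(probs) <- object$levels
  label <- object$levels[max.col(probs, ties.method = "first")]
  out <- tibble::as_tibble(as.data.frame(probs))
  out$label <- label
  out[, c("label", object$levels)]
}
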