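#' Height-normalize a skeleton sequence
#'
#' Uniformly rescales the skeleton so its median head-to-foot vertical
#' extent is 1 unit and translates it so the mean pelvis position is the
#' origin. A single scalar scale preserves aspect ratio, so body
#' proportions and sway ratios survive while stature — the structural cue
#' the point-light display must not leak — is removed.
#'
#' @param seq A [skeleton_sequence()].
#' @return The normalized `skeleton_sequence` (dimensionless units).
#' @export
height_normalize <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  pos <- seq$positions
  head_y <- pos[, "head", "y"]
  foot_y <- pmin(pos[, "foot_l", "y"], pos[, "foot_r", "y"])
  extent <- stats::median(head_y - foot_y)
  if (!is.finite(extent) || extent <= 1e-12) {
    stop("degenerate skeleton: zero head-to-foot vertical extent", call. = FALSE)
  }
  pelvis_mean <- colMeans(pos[, "pelvis", , drop = FALSE][, 1, ])
  for (a in 1:3) pos[, , a] <- (pos[, , a] - pelvis_mean[a]) / extent
  set_positions(seq, pos)
}

#' Centered moving-average smoothing
#'
#' Smooths every coordinate with a centered moving average (default 5
#' frames). Edges use a shrinking (truncated) centered window so sequence
#' length is preserved; constants and affine ramps pass through unchanged on
#' interior frames.
#'
#' @param seq A [skeleton_sequence()] or 2D projection.
#' @param window Odd window length in frames (default 5).
#' @return Smoothed sequence of the same length.
#' @export
smooth_moving_average <- function(seq, window = 5) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- n_frames(seq)
  if (n < window) stop("sequence shorter than smoothing window", call. = FALSE)
  half <- floor(window / 2)
  pos <- seq$positions
  d <- dim(pos)
  flat <- matrix(pos, nrow = n)
  # cumulative-sum moving average with shrinking edge windows
  cs <- rbind(0, apply(flat, 2, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  out <- array(sm, dim = d, dimnames = dimnames(pos))
  seq$positions <- out
  seq
}

#' Differentiate a sequence into joint velocities
#'
#' Forward difference of adjacent frames scaled by the frame rate, giving
#' per-joint velocities in m/s. The output is length-preserving: the final
#' difference row is repeated so velocity and position windows align
#' one-to-one for a given window specification.
#'
#' @param seq A [skeleton_sequence()] or 2D projection.
#' @param fps Frames per second; defaults to the sequence's `fps`.
#' @return Sequence of the same shape whose positions hold velocities.
#' @export
differentiate <- function(seq, fps = seq$fps) {
  n <- n_frames(seq)
  if (n < 2) stop("need at least 2 frames to differentiate", call. = FALSE)
  if (!is.finite(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  pos <- seq$positions
  d <- dim(pos)
  flat <- matrix(pos, nrow = n)
  vel <- (flat[-1, , drop = FALSE] - flat[-n, , drop = FALSE]) * fps
  vel <- rbind(vel, vel[n - 1L, , drop = FALSE])
  seq$positions <- array(vel, dim = d, dimnames = dimnames(pos))
  seq
}

#' Project to the coronal plane
#'
#' Drops the anterior-posterior (z) axis, keeping lateral (x) and vertical
#' (y) coordinates — the walker as seen head-on, emphasizing lateral sway.
#' Per-frame cardinality drops from 60 to 40. Idempotent.
#'
#' @param seq A [skeleton_sequence()] (or an already-projected sequence,
#'   returned unchanged).
#' @return A `skeleton_sequence_2d` with a frames x 20 x 2 position array.
#' @export
project_coronal <- function(seq) {
  if (inherits(seq, "skeleton_sequence_2d")) {
    return(seq)
  }
  stopifnot(inherits(seq, "skeleton_sequence"))
  seq$positions <- seq$positions[, , c("x", "y"), drop = FALSE]
  class(seq) <- "skeleton_sequence_2d"
  seq
}

#' Exposure-duration window specification
#'
#' Windows are defined in frames, `10 * k` for `k = 1..10`, mirroring ten
#' exposure durations stepped evenly from the shortest to the longest clip.
#' The nominal duration label is `n_frames / fps` at the capture rate.
#'
#' @param k Window index in `1..10`.
#' @param fps Frame rate used for the nominal duration label.
#' @return List with `k`, `n_frames`, `nominal_duration`.
#' @export
window_spec <- function(k, fps = 24) {
  if (!k %in% 1:10) stop("k must be in 1..10", call. = FALSE)
  list(k = as.integer(k), n_frames = 10L * as.integer(k), nominal_duration = 10 * k / fps)
}

#' Split a sequence into fixed-length windows
#'
#' Cuts the sequence into consecutive windows of `spec$n_frames` frames,
#' non-overlapping by default. Each window is a `frames x D` matrix (D = 60
#' for 3D, 40 for coronal sequences). A sequence shorter than one window
#' yields an empty list with a warning.
#'
#' @param seq A skeleton sequence (3D or 2D), or a frames x D matrix.
#' @param spec A [window_spec()] (or bare frame count).
#' @param stride Hop between window starts in frames; defaults to the
#'   window length (non-overlapping).
#' @return List of `n_frames x D` matrices.
#' @export
window_split <- function(seq, spec, stride = NULL) {
  nf <- if (is.list(spec)) spec$n_frames else as.integer(spec)
  stride <- stride %||% nf
  mat <- if (is.matrix(seq)) seq else as_frame_matrix(seq)
  n <- nrow(mat)
  if (n < nf) {
    warning("sequence shorter than one window; returning empty list")
    return(list())
  }
  starts <- seq(1L, n - nf + 1L, by = stride)
  lapply(starts, function(s) mat[s:(s + nf - 1L), , drop = FALSE])
}

#' Fit feature scaling statistics on training data
#'
#' Standardizes each feature to zero mean and unit SD, then min-max maps the
#' standardized values to `[-1, 1]` using the training extrema. All
#' statistics are frozen from the training partition only; applying the
#' scaler to held-out data may yield values outside `[-1, 1]`, which are
#' deliberately not clipped. Zero-variance features are flagged and mapped
#' to 0.
#'
#' @param x Numeric matrix, rows = training samples, columns = features.
#' @return A `scaler_stats` object.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  zero_var <- !is.finite(sd_) | sd_ <= 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance feature(s) retained as 0")
    sd_[zero_var] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  zmin <- apply(z, 2, min)
  zmax <- apply(z, 2, max)
  span <- zmax - zmin
  span[span <= 0] <- 1
  structure(
    list(mean = mu, sd = sd_, min = zmin, max = zmax, span = span, zero_var = zero_var),
    class = "scaler_stats"
  )
}

#' Apply frozen scaling statistics
#'
#' @param stats A `scaler_stats` from [fit_scaler()].
#' @param x Matrix with the same feature columns as the fit data.
#' @return Scaled matrix: z-scored with training mean/SD, then mapped so the
#'   training extrema land on -1 and +1.
#' @export
apply_scaler <- function(stats, x) {
  stopifnot(inherits(stats, "scaler_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean)) {
    stop(sprintf(
      "scaler fitted on %d features, got %d", length(stats$mean), ncol(x)
    ), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
  out <- sweep(sweep(z, 2, stats$min), 2, stats$span, "/") * 2 - 1
  if (any(stats$zero_var)) out[, stats$zero_var] <- 0
  out
}
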