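#' Four-statistic static summary of a windowed gait sample
#'
#' Collapses a `frames x D` window into `4 * D` numbers: the minimum,
#' maximum, mean, and population standard deviation of each dimension,
#' concatenated dimension-major. The summary is invariant to frame order —
#' the defining contrast with sequence models, which read temporal
#' structure.
#'
#' @param window Numeric `frames x D` matrix (one window of flattened
#'   frames).
#' @return Named numeric vector of length `4 * D` in the order
#'   `(min, max, mean, sd)` per dimension.
#' @export
static_summary <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) == 0 || ncol(window) == 0) {
    stop("static_summary requires a non-empty window", call. = FALSE)
  }
  n <- nrow(window)
  mins <- apply(window, 2, min)
  maxs <- apply(window, 2, max)
  means <- colMeans(window)
  # population (n) standard deviation, fixed for reproducibility
  sds <- sqrt(colMeans(window^2) - means^2)
  sds[sds < 0 | is.na(sds)] <- 0
  out <- as.vector(rbind(mins, maxs, means, sds))
  cn <- colnames(window) %||% paste0("d", seq_len(ncol(window)))
  names(out) <- as.vector(outer(c("min", "max", "mean", "sd"), cn, function(s, d) paste(d, s, sep = "_")))
  out
}

# Local maxima of `x` with a minimum index separation, greedy by height.
find_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3) {
    return(integer(0))
  }
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) {
    return(integer(0))
  }
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Dominant stride period (s) from the autocorrelation of pelvis lateral sway.
estimate_cycle_period <- function(seq) {
  x <- seq$positions[, "pelvis", "x"]
  fps <- seq$fps
  if (stats::sd(x) < 1e-9) {
    stop("no gait detected: pelvis sway has no variance", call. = FALSE)
  }
  max_lag <- min(length(x) - 2L, ceiling(3 * fps)) # periods up to 3 s
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  min_lag <- max(3L, floor(0.5 * fps)) # shortest credible stride ~0.5 s
  idx <- find_peaks(ac, min_sep = 2L)
  idx <- idx[idx >= min_lag + 1L] # acf index 1 is lag 0
  if (!length(idx) || max(ac[idx]) < 0.2) {
    stop("no gait detected: pelvis sway is not periodic", call. = FALSE)
  }
  best <- idx[which.max(ac[idx])]
  (best - 1L) / fps
}

#' Detect heel-strike and toe-off events
#'
#' Marker-based gait event detection for treadmill data: per foot, heel
#' strike is a local maximum of the 5-frame-smoothed anterior position of
#' the foot relative to the pelvis, and toe-off is the subsequent local
#' minimum before the next heel strike. Candidate peaks closer than 0.4
#' estimated stride periods are suppressed; the period is estimated from
#' the dominant autocorrelation lag of pelvis lateral sway.
#'
#' @param seq A 3D [skeleton_sequence()] containing at least one full gait
#'   cycle (typically height-normalized first; the detector only uses
#'   relative positions, so either works).
#' @return A `gait_events` object: per foot, numeric vectors `heel_strikes`
#'   and `toe_offs` (seconds), alternating HS -> TO -> HS; plus the
#'   estimated `cycle_period`.
#' @export
detect_gait_events <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  period <- estimate_cycle_period(seq)
  fps <- seq$fps
  sm <- smooth_moving_average(seq, 5)
  t <- seq$timestamps
  events <- list()
  for (side in c("l", "r")) {
    z <- sm$positions[, paste0("foot_", side), "z"] - sm$positions[, "pelvis", "z"]
    min_sep <- max(2L, floor(0.4 * period * fps))
    hs_idx <- find_peaks(z, min_sep)
    if (length(hs_idx) < 2) {
      stop("no gait detected: fewer than two heel strikes for foot_", side,
        call. = FALSE
      )
    }
    to_idx <- integer(0)
    hs_keep <- integer(0)
    for (j in seq_len(length(hs_idx) - 1L)) {
      span <- (hs_idx[j] + 1L):(hs_idx[j + 1L] - 1L)
      if (length(span) < 3) next
      to_idx <- c(to_idx, span[which.min(z[span])])
      hs_keep <- c(hs_keep, hs_idx[j])
    }
    events[[side]] <- list(
      heel_strikes = t[c(hs_keep, hs_idx[length(hs_idx)])],
      toe_offs = t[to_idx]
    )
  }
  structure(
    list(l = events$l, r = events$r, cycle_period = period),
    class = "gait_events"
  )
}

# Knee flexion time course in degrees for one leg, from joint positions:
# 180 degrees minus the hip-knee-ankle angle.
knee_flexion_signal <- function(seq, side) {
  hip <- seq$positions[, paste0("hip_", side), ]
  knee <- seq$positions[, paste0("knee_", side), ]
  ankle <- seq$positions[, paste0("ankle_", side), ]
  v1 <- hip - knee
  v2 <- ankle - knee
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  180 - acos(cosang) * 180 / pi
}

#' Twelve clinical spatiotemporal gait metrics
#'
#' Estimates, from one session's trajectories and its detected gait events,
#' the spatiotemporal metric set used for clinical gait description:
#' stride length (belt-referenced, from twice the per-stride anterior
#' excursion of the ankle relative to the pelvis), cadence (steps/min),
#' walking speed (`cadence / 120 * stride_length`), step length,
#' single- and double-support fractions (from the overlap of contralateral
#' stance intervals), per-leg stance:swing ratios, and per-leg
#' time-averaged knee flexion during stance and swing.
#'
#' @param seq The 3D [skeleton_sequence()] the events came from.
#' @param events A `gait_events` object from [detect_gait_events()].
#' @return Named numeric vector of exactly 12 metrics (same names as
#'   [ground_truth_metrics()]).
#' @export
clinical_metrics <- function(seq, events) {
  stopifnot(inherits(seq, "skeleton_sequence"), inherits(events, "gait_events"))
  t <- seq$timestamps
  sm <- smooth_moving_average(seq, 5)

  all_hs <- sort(c(events$l$heel_strikes, events$r$heel_strikes))
  if (length(all_hs) < 3) stop("need at least 2 ipsilateral heel strikes", call. = FALSE)
  elapsed <- all_hs[length(all_hs)] - all_hs[1]
  cadence <- 60 * (length(all_hs) - 1) / elapsed

  stride_excursion <- function(side) {
    z <- sm$positions[, paste0("ankle_", side), "z"] - sm$positions[, "pelvis", "z"]
    hs <- events[[side]]$heel_strikes
    exc <- vapply(seq_len(length(hs) - 1L), function(j) {
      sel <- t >= hs[j] & t <= hs[j + 1L]
      diff(range(z[sel]))
    }, numeric(1))
    mean(exc)
  }
  stride_len <- 2 * mean(c(stride_excursion("l"), stride_excursion("r")))

  stance_fraction <- function(side) {
    ev <- events[[side]]
    hs <- ev$heel_strikes
    stance <- numeric(0)
    for (j in seq_along(ev$toe_offs)) {
      stride_t <- hs[j + 1L] - hs[j]
      stance <- c(stance, (ev$toe_offs[j] - hs[j]) / stride_t)
    }
    mean(stance)
  }
  st_l <- stance_fraction("l")
  st_r <- stance_fraction("r")
  if (any(!is.finite(c(st_l, st_r))) || any(c(st_l, st_r) <= 0 | c(st_l, st_r) >= 1)) {
    stop("inconsistent gait events: stance fractions outside (0, 1)", call. = FALSE)
  }

  in_stance <- function(side) {
    ev <- events[[side]]
    out <- rep(NA, length(t)) # NA outside the observed event span
    span <- t >= ev$heel_strikes[1] & t <= ev$heel_strikes[length(ev$heel_strikes)]
    out[span] <- FALSE
    for (j in seq_along(ev$toe_offs)) {
      out[t >= ev$heel_strikes[j] & t < ev$toe_offs[j]] <- TRUE
    }
    out
  }
  sl <- in_stance("l")
  sr <- in_stance("r")
  both_known <- !is.na(sl) & !is.na(sr)
  double_support <- mean(sl[both_known] & sr[both_known])
  single_support <- mean(xor(sl[both_known], sr[both_known]))

  knee_phase_mean <- function(side) {
    flex <- knee_flexion_signal(seq, side)
    stance <- in_stance(side)
    c(
      stance = mean(flex[which(stance)]),
      swing = mean(flex[which(!stance)])
    )
  }
  kl <- knee_phase_mean("l")
  kr <- knee_phase_mean("r")

  c(
    stride_length = stride_len,
    cadence = cadence,
    speed = cadence / 120 * stride_len,
    step_length = stride_len / 2,
    single_support = single_support,
    double_support = double_support,
    stance_swing_ratio_l = st_l / (1 - st_l),
    stance_swing_ratio_r = st_r / (1 - st_r),
    knee_flex_stance_l = kl[["stance"]],
    knee_flex_stance_r = kr[["stance"]],
    knee_flex_swing_l = kl[["swing"]],
    knee_flex_swing_r = kr[["swing"]]
  )
}
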