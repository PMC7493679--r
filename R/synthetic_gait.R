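#' Per-subject gait model parameters
#'
#' Ground-truth generating parameters for one synthetic walker. These are the
#' oracle for metric-recovery tests: every spatiotemporal quantity the
#' clinical feature extractor estimates from trajectories has a closed form
#' in these parameters (see [ground_truth_metrics()]).
#'
#' @param subject_id Subject identifier string.
#' @param gender `"M"` or `"F"`.
#' @param gait_cycle_period Full stride period in seconds (two steps); must
#'   lie in `[0.8, 2.4]`.
#' @param stride_length Meters advanced (on the virtual belt) per stride.
#' @param shoulder_sway_amp,hip_sway_amp Lateral sway amplitudes in meters of
#'   the shoulder girdle and pelvis. Their ratio is the planted dynamic
#'   gender cue.
#' @param vertical_bounce_amp Vertical pelvis oscillation amplitude (m), at
#'   twice the stride frequency.
#' @param arm_swing_amp Arm swing angular amplitude in radians.
#' @param knee_flexion_max Peak swing-phase knee flexion in degrees.
#' @param shoulder_width,hip_width Girdle widths in meters (structural cue).
#' @param height Stature in meters; limb segment lengths are standard
#'   anthropometric fractions of it.
#' @param duty_factor Fraction of the stride each foot spends in stance.
#' @param noise_sd Per-coordinate additive Gaussian jitter SD in meters,
#'   emulating depth-sensor noise.
#' @param segment_lengths Optional named list of limb segment lengths in
#'   meters; defaults derived from `height`.
#' @param weight,age Subject metadata (kg, years); unused by the kinematics.
#' @return An object of class `gait_params`.
#' @export
gait_params <- function(subject_id, gender, gait_cycle_period = 1.6,
                        stride_length = 1.2, shoulder_sway_amp = 0.045,
                        hip_sway_amp = 0.045, vertical_bounce_amp = 0.03,
                        arm_swing_amp = 0.35, knee_flexion_max = 60,
                        shoulder_width = 0.36, hip_width = 0.33,
                        height = 1.7, duty_factor = 0.62, noise_sd = 0.005,
                        segment_lengths = NULL, weight = NA_real_,
                        age = NA_real_) {
  gender <- match.arg(gender, c("M", "F"))
  pos <- c(
    gait_cycle_period = gait_cycle_period,
    shoulder_width = shoulder_width, hip_width = hip_width, height = height
  )
  if (any(pos <= 0)) {
    stop("all lengths and periods must be strictly positive: ",
      paste(names(pos)[pos <= 0], collapse = ", "),
      call. = FALSE
    )
  }
  nonneg <- c(
    stride_length = stride_length,
    shoulder_sway_amp = shoulder_sway_amp, hip_sway_amp = hip_sway_amp,
    vertical_bounce_amp = vertical_bounce_amp, arm_swing_amp = arm_swing_amp,
    knee_flexion_max = knee_flexion_max, noise_sd = noise_sd
  )
  if (any(nonneg < 0)) {
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)
  }
  if (gait_cycle_period < 0.8 || gait_cycle_period > 2.4) {
    stop("gait_cycle_period must lie in [0.8, 2.4] s", call. = FALSE)
  }
  if (duty_factor <= 0.5 || duty_factor >= 1) {
    stop("duty_factor must lie in (0.5, 1) for walking gait", call. = FALSE)
  }
  if (is.null(segment_lengths)) {
    segment_lengths <- default_segment_lengths(height)
  }
  structure(
    list(
      subject_id = as.character(subject_id), gender = gender,
      gait_cycle_period = gait_cycle_period, stride_length = stride_length,
      shoulder_sway_amp = shoulder_sway_amp, hip_sway_amp = hip_sway_amp,
      vertical_bounce_amp = vertical_bounce_amp, arm_swing_amp = arm_swing_amp,
      knee_flexion_max = knee_flexion_max, shoulder_width = shoulder_width,
      hip_width = hip_width, height = height, duty_factor = duty_factor,
      noise_sd = noise_sd, segment_lengths = segment_lengths,
      weight = weight, age = age
    ),
    class = "gait_params"
  )
}

# Standard anthropometric segment-length fractions of stature.
default_segment_lengths <- function(height) {
  list(
    thigh = 0.245 * height,
    shank = 0.246 * height,
    foot = 0.120 * height,
    ankle_height = 0.039 * height,
    upper_arm = 0.186 * height,
    forearm = 0.146 * height,
    hand = 0.090 * height,
    pelvis_to_spine = 0.140 * height,
    spine_to_neck = 0.180 * height,
    neck_to_head = 0.100 * height
  )
}

#' Gender-conditional generating distributions for a synthetic cohort
#'
#' Each gait parameter is drawn from a gender-conditional truncated Gaussian.
#' The `cue` argument controls where gender information is planted:
#' * `"both"` (default): dynamic cue (shoulder/hip sway ratio, male mean 1.3
#'   vs female 0.7, SD 0.25) plus structural cues (stature per the study
#'   population's gender means; shoulder:hip width ratio 1.15 vs 0.95).
#' * `"dynamic"`: the sway-ratio cue only; stature and proportions are drawn
#'   from pooled gender-neutral distributions.
#' * `"height_only"`: genders differ only in stature, the cue height
#'   normalization removes.
#' * `"none"`: all parameters pooled; labels carry no information.
#'
#' @param cue Where the gender effect lives; see Details.
#' @param sway_ratio_m,sway_ratio_f,sway_ratio_sd Means and SD of the
#'   shoulder/hip sway amplitude ratio by gender.
#' @param noise_sd Trajectory jitter SD in meters passed to every subject.
#' @return A named list of per-parameter `(male, female, sd, lower, upper)`
#'   specifications consumed by [sample_cohort()].
#' @export
effect_config <- function(cue = c("both", "dynamic", "height_only", "none"),
                          sway_ratio_m = 1.3, sway_ratio_f = 0.7,
                          sway_ratio_sd = 0.25, noise_sd = 0.005) {
  cue <- match.arg(cue)
  par2 <- function(m, f, sd, lo, hi) list(male = m, female = f, sd = sd, lower = lo, upper = hi)
  pooled <- function(m, sd, lo, hi) par2(m, m, sd, lo, hi)
  cfg <- list(
    # stature: study-population means/SDs truncated to the stated ranges
    height = par2(1.7623, 1.2856, NA, NA, NA),
    width_ratio = par2(1.15, 0.95, 0.06, 0.7, 1.5),
    sway_ratio = par2(sway_ratio_m, sway_ratio_f, sway_ratio_sd, 0.1, 3.0),
    hip_sway_amp = pooled(0.045, 0.008, 0.015, 0.09),
    gait_cycle_period = pooled(1.6, 0.12, 0.8, 2.4),
    stride_length = pooled(1.2, 0.12, 0.6, 1.8),
    vertical_bounce_amp = pooled(0.030, 0.005, 0.005, 0.06),
    arm_swing_amp = pooled(0.35, 0.07, 0.05, 0.8),
    knee_flexion_max = pooled(60, 6, 30, 80),
    duty_factor = pooled(0.62, 0, 0.55, 0.75),
    weight = par2(80.49, 73.30, NA, 45, 120),
    age = par2(26.06, 21.29, NA, 18, 50),
    noise_sd = noise_sd,
    cue = cue
  )
  cfg$height$sd_male <- 0.3243
  cfg$height$sd_female <- 0.2351
  cfg$height$range_male <- c(1.44, 2.08)
  cfg$height$range_female <- c(1.29, 1.52)
  cfg$weight$sd_male <- 2.86
  cfg$weight$sd_female <- 4.59
  cfg$age$sd_male <- 6.42
  cfg$age$sd_female <- 1.23
  if (cue %in% c("dynamic", "none")) {
    cfg$height <- par2(1.65, 1.65, NA, NA, NA)
    cfg$height$sd_male <- cfg$height$sd_female <- 0.10
    cfg$height$range_male <- cfg$height$range_female <- c(1.40, 1.95)
    cfg$width_ratio <- pooled(1.05, 0.06, 0.7, 1.5)
  }
  if (cue %in% c("height_only", "none")) {
    cfg$sway_ratio <- pooled(1.0, sway_ratio_sd, 0.1, 3.0)
    if (cue == "height_only") cfg$width_ratio <- pooled(1.05, 0.06, 0.7, 1.5)
  }
  cfg
}

draw_par <- function(cfg, name, gender, n = 1) {
  p <- cfg[[name]]
  if (!is.null(p$sd_male)) { # gender-specific sd / range form
    sd <- if (gender == "M") p$sd_male else p$sd_female
    rng <- if (gender == "M") p$range_male %||% c(p$lower, p$upper) else p$range_female %||% c(p$lower, p$upper)
    mu <- if (gender == "M") p$male else p$female
    return(rtruncnorm(n, mu, sd, rng[1], rng[2]))
  }
  mu <- if (gender == "M") p$male else p$female
  rtruncnorm(n, mu, p$sd, p$lower, p$upper)
}

#' Sample a synthetic walker cohort
#'
#' Draws per-subject [gait_params()] from the gender-conditional
#' distributions in `config`. The default cohort mirrors the study
#' population: 26 male and 15 female subjects, 6 one-minute treadmill
#' sessions each at 24 fps.
#'
#' @param n_male,n_female Subject counts per gender (non-negative, not both
#'   zero).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param config Generating distributions from [effect_config()].
#' @param sessions_per_subject,session_duration,fps Session layout defaults
#'   (6 sessions, 60 s, 24 fps).
#' @return An object of class `cohort_spec`: list with `subjects` (list of
#'   `gait_params`), the session layout fields, and `seed`.
#' @export
sample_cohort <- function(n_male = 26, n_female = 15, seed = 1,
                          config = effect_config(),
                          sessions_per_subject = 6, session_duration = 60,
                          fps = 24) {
  if (n_male < 0 || n_female < 0 || (n_male + n_female) == 0) {
    stop("invalid cohort: need non-negative counts and at least one subject",
      call. = FALSE
    )
  }
  genders <- c(rep("M", n_male), rep("F", n_female))
  subjects <- with_seed(seed, {
    lapply(seq_along(genders), function(i) {
      g <- genders[i]
      height <- draw_par(config, "height", g)
      hip_sway <- draw_par(config, "hip_sway_amp", g)
      sway_ratio <- draw_par(config, "sway_ratio", g)
      hip_width <- 0.191 * height * rtruncnorm(1, 1, 0.04, 0.85, 1.15)
      gait_params(
        subject_id = sprintf("S%03d", i),
        gender = g,
        gait_cycle_period = draw_par(config, "gait_cycle_period", g),
        stride_length = draw_par(config, "stride_length", g),
        hip_sway_amp = hip_sway,
        shoulder_sway_amp = hip_sway * sway_ratio,
        vertical_bounce_amp = draw_par(config, "vertical_bounce_amp", g),
        arm_swing_amp = draw_par(config, "arm_swing_amp", g),
        knee_flexion_max = draw_par(config, "knee_flexion_max", g),
        hip_width = hip_width,
        shoulder_width = hip_width * draw_par(config, "width_ratio", g),
        height = height,
        duty_factor = draw_par(config, "duty_factor", g),
        noise_sd = config$noise_sd,
        weight = draw_par(config, "weight", g),
        age = draw_par(config, "age", g)
      )
    })
  })
  structure(
    list(
      subjects = subjects,
      sessions_per_subject = sessions_per_subject,
      session_duration = session_duration,
      fps = fps,
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  g <- vapply(x$subjects, `[[`, "", "gender")
  cat(sprintf(
    "<cohort_spec> %d subjects (%d M, %d F), %d sessions x %g s @ %g fps, seed %d\n",
    length(g), sum(g == "M"), sum(g == "F"),
    x$sessions_per_subject, x$session_duration, x$fps, x$seed
  ))
  invisible(x)
}

# Asymmetric stride waveform: cosine time-warped so the descent (stance,
# heel strike at u = 0 to toe-off at u = duty) occupies `duty` of the cycle
# and the ascent (swing) the remainder. Period and fundamental preserved.
warped_cos <- function(u, duty) {
  u <- u %% 1
  g <- ifelse(u < duty, 0.5 * u / duty, 0.5 + 0.5 * (u - duty) / (1 - duty))
  cospi(2 * g)
}

# Double-bump knee flexion time course (radians): small stance bump
# (30% of peak) then the main swing bump peaking at knee_flexion_max.
knee_flexion_course <- function(u, duty, kmax_rad) {
  u <- u %% 1
  stance <- u < duty
  out <- numeric(length(u))
  out[stance] <- 0.3 * kmax_rad * sinpi(u[stance] / duty)^2
  out[!stance] <- kmax_rad * sinpi((u[!stance] - duty) / (1 - duty))^2
  out
}

#' Generate one synthetic walking session
#'
#' Drives a 20-joint kinematic chain with truncated-Fourier joint-angle time
#' courses at the stride fundamental: pelvis lateral sway at stride
#' frequency, vertical bounce at twice stride frequency, shoulder girdle
#' counter-sway phase-offset by pi from the pelvis, legs in antiphase with a
#' stance/swing time-warp set by the duty factor, arms in antiphase with
#' their ipsilateral legs, and a double-bump knee-flexion course peaking at
#' `knee_flexion_max`. The walker is treadmill-bound (no anterior drift).
#' I.i.d. Gaussian jitter of SD `params$noise_sd` is added per coordinate.
#'
#' @param params A [gait_params()] object.
#' @param duration Session length in seconds (> 0).
#' @param fps Frames per second (> 0).
#' @param seed Integer seed for the jitter; output is deterministic given
#'   `(params, seed)`.
#' @param subject_id,session_id Metadata overrides; default from `params`.
#' @return A [skeleton_sequence()] with `round(duration * fps)` frames.
#' @export
generate_walk <- function(params, duration = 60, fps = 24, seed = 1,
                          subject_id = params$subject_id, session_id = "1") {
  stopifnot(inherits(params, "gait_params"))
  if (duration <= 0 || fps <= 0) {
    stop("duration and fps must be positive", call. = FALSE)
  }
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  T <- params$gait_cycle_period
  u_l <- (t / T) %% 1 # left-leg cycle variable, heel strike at 0
  u_r <- (t / T + 0.5) %% 1 # right leg in antiphase
  phi <- 2 * pi * t / T
  seg <- params$segment_lengths
  d <- params$duty_factor

  leg_len <- seg$thigh + seg$shank
  hip_y0 <- leg_len + seg$ankle_height
  # hip flexion amplitude realizing the configured stride length
  a_hip <- asin(min(params$stride_length / (4 * leg_len), 0.95))
  kmax <- params$knee_flexion_max * pi / 180

  pelvis_x <- params$hip_sway_amp * sin(phi)
  pelvis_y <- hip_y0 + 0.04 * params$height + params$vertical_bounce_amp * sin(2 * phi)
  bounce <- params$vertical_bounce_amp * sin(2 * phi)
  neck_x <- -params$shoulder_sway_amp * sin(phi) # counter-sway, phase pi

  pos <- array(0, dim = c(n, 20, 3))
  jidx <- setNames(seq_len(20L), canonical_joints())
  put <- function(joint, x, y, z) {
    pos[, jidx[[joint]], 1] <<- x
    pos[, jidx[[joint]], 2] <<- y
    pos[, jidx[[joint]], 3] <<- z
  }

  spine_y <- hip_y0 + seg$pelvis_to_spine + bounce
  neck_y <- hip_y0 + seg$pelvis_to_spine + seg$spine_to_neck + bounce
  head_y <- neck_y + seg$neck_to_head
  put("pelvis", pelvis_x, pelvis_y, 0)
  put("spine_mid", (pelvis_x + neck_x) / 2, spine_y, 0)
  put("neck", neck_x, neck_y, 0)
  put("head", neck_x, head_y, 0)

  leg <- function(u, side_sign) {
    hip_x <- pelvis_x + side_sign * params$hip_width / 2
    hip_y <- hip_y0 + bounce
    # hip-to-ankle line angle from vertical (+ anterior); knee flexion is
    # realized by two-link inverse kinematics about that line, so the
    # ankle's anterior extrema fall exactly at heel strike (u = 0) and
    # toe-off (u = duty), where flexion vanishes.
    th <- a_hip * warped_cos(u, d)
    tk <- knee_flexion_course(u, d, kmax)
    dd <- sqrt(seg$thigh^2 + seg$shank^2 + 2 * seg$thigh * seg$shank * cos(tk))
    beta <- acos(pmin(1, pmax(-1, (seg$thigh^2 + dd^2 - seg$shank^2) / (2 * seg$thigh * dd))))
    tt <- th + beta # thigh angle; knee displaced anteriorly when flexed
    knee_y <- hip_y - seg$thigh * cos(tt)
    knee_z <- seg$thigh * sin(tt)
    ankle_y <- hip_y - dd * cos(th)
    ankle_z <- dd * sin(th)
    list(
      hip = cbind(hip_x, hip_y, 0),
      knee = cbind(hip_x, knee_y, knee_z),
      ankle = cbind(hip_x, ankle_y, ankle_z),
      foot = cbind(hip_x, ankle_y - 0.6 * seg$ankle_height, ankle_z + seg$foot)
    )
  }
  L <- leg(u_l, -1)
  R <- leg(u_r, +1)
  for (side in c("l", "r")) {
    ch <- if (side == "l") L else R
    put(paste0("hip_", side), ch$hip[, 1], ch$hip[, 2], ch$hip[, 3])
    put(paste0("knee_", side), ch$knee[, 1], ch$knee[, 2], ch$knee[, 3])
    put(paste0("ankle_", side), ch$ankle[, 1], ch$ankle[, 2], ch$ankle[, 3])
    put(paste0("foot_", side), ch$foot[, 1], ch$foot[, 2], ch$foot[, 3])
  }

  arm <- function(arm_phase_sign, side_sign) {
    # antiphase with the ipsilateral leg's anterior excursion
    ta <- arm_phase_sign * params$arm_swing_amp * cos(phi)
    sh_x <- neck_x + side_sign * params$shoulder_width / 2
    sh_y <- neck_y - 0.02 * params$height
    el_x <- sh_x
    el_y <- sh_y - seg$upper_arm * cos(ta)
    el_z <- seg$upper_arm * sin(ta)
    tf <- ta + 0.35 # slight constant elbow flexion
    wr_y <- el_y - seg$forearm * cos(tf)
    wr_z <- el_z + seg$forearm * sin(tf)
    hd_y <- wr_y - seg$hand * cos(tf)
    hd_z <- wr_z + seg$hand * sin(tf)
    list(
      shoulder = cbind(sh_x, sh_y, 0), elbow = cbind(el_x, el_y, el_z),
      wrist = cbind(el_x, wr_y, wr_z), hand = cbind(el_x, hd_y, hd_z)
    )
  }
  AL <- arm(-1, -1) # left arm antiphase to left leg (phase 0)
  AR <- arm(+1, +1)
  for (side in c("l", "r")) {
    ch <- if (side == "l") AL else AR
    put(paste0("shoulder_", side), ch$shoulder[, 1], ch$shoulder[, 2], ch$shoulder[, 3])
    put(paste0("elbow_", side), ch$elbow[, 1], ch$elbow[, 2], ch$elbow[, 3])
    put(paste0("wrist_", side), ch$wrist[, 1], ch$wrist[, 2], ch$wrist[, 3])
    put(paste0("hand_", side), ch$hand[, 1], ch$hand[, 2], ch$hand[, 3])
  }

  if (params$noise_sd > 0) {
    pos <- pos + with_seed(seed, array(rnorm(length(pos), 0, params$noise_sd), dim = dim(pos)))
  }
  skeleton_sequence(
    timestamps = t, positions = pos,
    subject_id = subject_id, session_id = session_id,
    gender = params$gender, fps = fps
  )
}

#' Closed-form clinical metrics implied by the generating model
#'
#' The oracle for metric-recovery tests: the twelve spatiotemporal gait
#' metrics the clinical feature extractor estimates from trajectories, here
#' computed exactly from the generating parameters. Cadence is
#' `120 / gait_cycle_period` steps/min, walking speed
#' `stride_length / gait_cycle_period`, stance and swing fractions follow
#' the configured duty factor, and the time-averaged knee flexion over a
#' phase equals half its sinusoidal-bump peak: `knee_flexion_max / 2` in
#' swing and `0.3 * knee_flexion_max / 2` in stance.
#'
#' @param params A [gait_params()] object.
#' @return Named numeric vector of 12 metrics (same names and order as
#'   [clinical_metrics()]).
#' @export
ground_truth_metrics <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  T <- params$gait_cycle_period
  d <- params$duty_factor
  c(
    stride_length = params$stride_length,
    cadence = 120 / T,
    speed = params$stride_length / T,
    step_length = params$stride_length / 2,
    single_support = 2 * (1 - d),
    double_support = 2 * d - 1,
    stance_swing_ratio_l = d / (1 - d),
    stance_swing_ratio_r = d / (1 - d),
    knee_flex_stance_l = 0.15 * params$knee_flexion_max,
    knee_flex_stance_r = 0.15 * params$knee_flexion_max,
    knee_flex_swing_l = 0.5 * params$knee_flexion_max,
    knee_flex_swing_r = 0.5 * params$knee_flexion_max
  )
}
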