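#' Subject table of a dataset
#'
#' @param dataset A `gait_dataset`.
#' @return Tibble with one row per walker: `subject_id`, `gender`.
#' @export
subject_table <- function(dataset) {
  stopifnot(inherits(dataset, "gait_dataset"))
  df <- tibble::tibble(
    subject_id = vapply(dataset, `[[`, "", "subject_id"),
    gender = vapply(dataset, `[[`, "", "gender")
  )
  dplyr::distinct(df)
}

#' Subject-wise stratified k-fold split
#'
#' Partitions walkers (never sessions or windows) into `k` folds of
#' near-equal size, stratified by gender, so no subject's data ever
#' appears in both train and test — the guard against identity leakage.
#'
#' @param x A `gait_dataset` or a data frame with `subject_id` and
#'   `gender` columns.
#' @param k Number of folds (default 10).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return List of `k` character vectors of test-fold subject ids.
#' @export
subject_kfold <- function(x, k = 10, seed = 1) {
  subjects <- if (inherits(x, "gait_dataset")) subject_table(x) else tibble::as_tibble(x)
  stopifnot(all(c("subject_id", "gender") %in% names(subjects)))
  subjects <- dplyr::distinct(subjects, .data$subject_id, .data$gender)
  n <- nrow(subjects)
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")", call. = FALSE)
  folds <- vector("list", k)
  counter <- 0L
  with_seed(seed, {
    for (g in unique(subjects$gender)) {
      ids <- sample(subjects$subject_id[subjects$gender == g])
      for (id in ids) {
        f <- (counter %% k) + 1L
        folds[[f]] <- c(folds[[f]], id)
        counter <- counter + 1L
      }
    }
  })
  folds
}

# Height-normalize then transform one sequence into the requested
# representation's frame matrix.
representation_matrix <- function(seq, representation) {
  base <- height_normalize(seq)
  switch(representation,
    position3d = ,
    static4 = ,
    clinical = as_frame_matrix(base),
    velocity3d = ,
    static4_velocity = as_frame_matrix(differentiate(smooth_moving_average(base, 5))),
    position2d = as_frame_matrix(project_coronal(base)),
    velocity2d = as_frame_matrix(differentiate(smooth_moving_average(project_coronal(base), 5))),
    stop("unknown representation: ", representation, call. = FALSE)
  )
}

is_static_rep <- function(representation) {
  representation %in% c("static4", "static4_velocity", "clinical")
}

# Windowed inputs for one (representation, window length) combination:
# for sequence representations a list of windows, for static4 variants a
# feature matrix of four first-order statistics per dimension, for
# clinical one metric vector per session.
prepare_inputs <- function(dataset, representation, n_frames_win, stride = NULL) {
  windows <- list()
  feats <- list()
  subj <- character(0)
  sess <- character(0)
  for (rec in dataset) {
    if (representation == "clinical") {
      base <- height_normalize(rec$sequence)
      ev <- detect_gait_events(base)
      feats[[length(feats) + 1L]] <- clinical_metrics(base, ev)
      subj <- c(subj, rec$subject_id)
      sess <- c(sess, rec$session_id)
      next
    }
    mat <- representation_matrix(rec$sequence, representation)
    ws <- window_split(mat, n_frames_win, stride)
    if (!length(ws)) next
    if (is_static_rep(representation)) {
      feats <- c(feats, lapply(ws, static_summary))
    } else {
      windows <- c(windows, ws)
    }
    subj <- c(subj, rep(rec$subject_id, length(ws)))
    sess <- c(sess, rep(rec$session_id, length(ws)))
  }
  if (is_static_rep(representation)) {
    list(
      features = do.call(rbind, feats), subject_id = subj, session_id = sess,
      kind = "static"
    )
  } else {
    list(windows = windows, subject_id = subj, session_id = sess, kind = "sequence")
  }
}

default_cells <- function(exp_id) {
  statics <- c("svm_linear", "svm_rbf", "svm_sigmoid", "rdf")
  switch(as.character(exp_id),
    "2" = tibble::tibble(family = "lstm", representation = "position3d"),
    "3" = tidyr::expand_grid(family = statics, representation = c("static4", "clinical")),
    "4" = dplyr::bind_rows(
      tibble::tibble(family = "lstm", representation = "velocity3d"),
      tidyr::expand_grid(family = statics, representation = "static4_velocity")
    ),
    "5" = tidyr::expand_grid(family = "lstm", representation = c("position2d", "velocity2d")),
    stop("unknown experiment id: ", exp_id, call. = FALSE)
  )
}

evaluate_split <- function(inputs, labels_by_subject, train_subj, test_subj,
                           family, lstm_hp, static_cfg, model_seed) {
  lab <- labels_by_subject[inputs$subject_id]
  tr <- inputs$subject_id %in% train_subj
  te <- inputs$subject_id %in% test_subj
  if (!any(te)) {
    return(NULL)
  }
  if (inputs$kind == "sequence") {
    train_w <- inputs$windows[tr]
    test_w <- inputs$windows[te]
    st <- fit_scaler(do.call(rbind, train_w))
    train_w <- lapply(train_w, function(w) apply_scaler(st, w))
    test_w <- lapply(test_w, function(w) apply_scaler(st, w))
    hp <- lstm_hp
    hp$seed <- model_seed
    model <- train_lstm(train_w, lab[tr], hp = hp, scaler = st)
    pred <- predict(model, test_w)
  } else {
    st <- fit_scaler(inputs$features[tr, , drop = FALSE])
    spec <- do.call(static_model_spec, c(list(family = family), static_cfg, list(seed = model_seed)))
    model <- train_static(
      suppressWarnings(apply_scaler(st, inputs$features[tr, , drop = FALSE])),
      lab[tr], spec,
      scaler = st
    )
    pred <- predict(model, suppressWarnings(apply_scaler(st, inputs$features[te, , drop = FALSE])))
  }
  truth <- lab[te]
  tibble::tibble(
    n_test = length(truth),
    n_correct = sum(pred$label == truth),
    accuracy = sum(pred$label == truth) / length(truth)
  )
}

#' Run an exposure-duration sweep experiment
#'
#' Orchestrates the benchmark's computational experiments over a dataset:
#' * `2` — LSTM on 3D joint positions;
#' * `3` — SVMs and the decision forest on the two static representations
#'   (four first-order statistics; clinical metrics);
#' * `4` — all families on velocity cues (5-frame smoothing, then temporal
#'   derivatives);
#' * `5` — LSTM on coronal (2D) position and velocity input.
#'
#' Each cell of the factorial (model family x representation x window
#' length x replicate x fold) is trained and scored under subject-wise
#' stratified cross-validation; replicates re-seed both fold assignment
#' and model initialization. Deterministic given `config$seed`.
#'
#' @param exp_id Experiment id in `2:5`.
#' @param dataset A `gait_dataset`.
#' @param config Optional overrides: `cells` (tibble of family /
#'   representation pairs), `ks` (window indices, default `1:10`),
#'   `replicates` (default 10), `folds` (default 10), `seed` (default 1),
#'   `lstm` (hyper-parameter overrides for [lstm_hyperparams()]), `static`
#'   (overrides for [static_model_spec()]), `window_stride`, and
#'   `permute_labels` (subject-level label permutation for null
#'   calibration, default `FALSE`).
#' @return Tibble of class `sweep_result`: one row per (family,
#'   representation, k, replicate, fold) with `n_test`, `n_correct`,
#'   `accuracy`.
#' @export
run_experiment <- function(exp_id, dataset, config = list()) {
  stopifnot(inherits(dataset, "gait_dataset"))
  cells <- config$cells %||% default_cells(exp_id)
  ks <- config$ks %||% 1:10
  replicates <- config$replicates %||% 10
  n_folds <- config$folds %||% 10
  seed <- config$seed %||% 1
  lstm_hp <- do.call(lstm_hyperparams, config$lstm %||% list())
  static_cfg <- config$static %||% list()
  permute <- isTRUE(config$permute_labels)

  subjects <- subject_table(dataset)
  true_labels <- stats::setNames(subjects$gender, subjects$subject_id)

  input_cache <- new.env(parent = emptyenv())
  get_inputs <- function(representation, nf) {
    key <- paste(representation, nf, sep = ":")
    if (!is.null(input_cache[[key]])) {
      return(input_cache[[key]])
    }
    inp <- prepare_inputs(dataset, representation, nf, config$window_stride)
    input_cache[[key]] <- inp
    inp
  }

  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- (seed + 1000L * r) %% .Machine$integer.max
    labels <- true_labels
    if (permute) {
      labels[] <- with_seed(rep_seed + 7L, sample(unname(true_labels)))
    }
    # stratify folds on the labels actually trained on: under label
    # permutation, stratifying on the true gender would leave the permuted
    # classes unbalanced across folds, and the train-majority class is then
    # systematically under-represented in the test fold - a finite-cohort
    # artifact that drags a label-uninformed classifier below chance
    fold_table <- tibble::tibble(
      subject_id = subjects$subject_id,
      gender = unname(labels[subjects$subject_id])
    )
    folds <- subject_kfold(fold_table, k = n_folds, seed = rep_seed)
    for (ci in seq_len(nrow(cells))) {
      family <- cells$family[ci]
      representation <- cells$representation[ci]
      ks_eff <- if (representation == "clinical") NA_integer_ else ks
      for (k in ks_eff) {
        nf <- if (is.na(k)) NA_integer_ else window_spec(k)$n_frames
        inputs <- get_inputs(representation, nf)
        for (f in seq_along(folds)) {
          test_subj <- folds[[f]]
          train_subj <- setdiff(subjects$subject_id, test_subj)
          res <- evaluate_split(
            inputs, labels, train_subj, test_subj, family,
            lstm_hp, static_cfg,
            model_seed = (rep_seed * 31L + f * 7919L + ci) %% .Machine$integer.max
          )
          if (is.null(res)) next
          rows[[length(rows) + 1L]] <- tibble::tibble(
            experiment_id = exp_id, family = family,
            representation = representation, k = k,
            replicate = r, fold = f,
            n_test = res$n_test, n_correct = res$n_correct,
            accuracy = res$accuracy
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Build a point-light stimulus clip from a skeleton sequence
#'
#' Maps the coronal projection of a (height-normalized) walker into a
#' walker box of 2.5 x 4 degrees of visual angle centered in a 6 x 8
#' degree stimulus field rendered on a 1920 x 1080 canvas: 20 white dots
#' of 5 px radius per frame. Returns the per-frame dot-coordinate table
#' (rendering to video is out of scope).
#'
#' @param seq A height-normalized [skeleton_sequence()].
#' @param exposure Optional clip length in seconds (from the sequence
#'   start). In `psychophysics` mode it must be one of 0.4, 1.5, 2.5,
#'   3.8 s — the exposure durations shown to human observers.
#' @param psychophysics Restrict `exposure` to the human-experiment set.
#' @param canvas_px Canvas size `c(width, height)` in pixels.
#' @param field_deg,walker_deg Stimulus field and walker box sizes in
#'   degrees `c(width, height)`.
#' @param dot_radius_px Dot radius in pixels.
#' @return Tibble of class `stimulus_clip`: `frame`, `time`, `joint`,
#'   `x_px`, `y_px`, with the display geometry in attributes.
#' @export
make_stimulus_clip <- function(seq, exposure = NULL, psychophysics = FALSE,
                               canvas_px = c(1920, 1080), field_deg = c(6, 8),
                               walker_deg = c(2.5, 4), dot_radius_px = 5) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (psychophysics) {
    allowed <- c(0.4, 1.5, 2.5, 3.8)
    if (is.null(exposure) || !any(abs(exposure - allowed) < 1e-9)) {
      stop("psychophysics exposures are restricted to 0.4, 1.5, 2.5, 3.8 s",
        call. = FALSE
      )
    }
  }
  proj <- project_coronal(seq)
  n <- n_frames(proj)
  if (!is.null(exposure)) {
    n <- min(n, round(exposure * seq$fps))
  }
  x <- proj$positions[seq_len(n), , "x"]
  y <- proj$positions[seq_len(n), , "y"]
  px_per_deg <- canvas_px[2] / field_deg[2]
  # height-normalized extent (1 unit) spans the walker box height
  scale <- walker_deg[2] * px_per_deg
  xmid <- (max(x) + min(x)) / 2
  ymid <- (max(y) + min(y)) / 2
  out <- tibble::tibble(
    frame = rep(seq_len(n), times = 20),
    time = rep(seq$timestamps[seq_len(n)], times = 20),
    joint = rep(canonical_joints(), each = n),
    x_px = canvas_px[1] / 2 + as.vector(x - xmid) * scale,
    y_px = canvas_px[2] / 2 - as.vector(y - ymid) * scale
  )
  attr(out, "dot_radius_px") <- dot_radius_px
  attr(out, "canvas_px") <- canvas_px
  attr(out, "field_deg") <- field_deg
  attr(out, "walker_deg") <- walker_deg
  attr(out, "fps") <- seq$fps
  class(out) <- c("stimulus_clip", class(out))
  out
}
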