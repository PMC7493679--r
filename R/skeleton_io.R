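#' Write a skeleton sequence to a CSV file
#'
#' One row per frame: a `t` column (seconds) followed by 60 coordinate
#' columns named `<joint>_<axis>` in canonical joint order. Coordinates are
#' serialized with 12 significant digits so a write/read round trip is
#' faithful to better than 1e-9 m. A JSON sidecar `<path>.meta.json` stores
#' subject, session, gender and fps.
#'
#' @param seq A valid [skeleton_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (dim(seq$positions)[3] != 3L) {
    stop("only full 3D sequences are written to disk", call. = FALSE)
  }
  mat <- as_frame_matrix(seq)
  df <- cbind(t = seq$timestamps, as.data.frame(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- apply(format(df, digits = 12, scientific = FALSE, trim = TRUE), 1,
    paste,
    collapse = ","
  )
  writeLines(body, con)
  jsonlite::write_json(
    list(
      subject_id = seq$subject_id, session_id = seq$session_id,
      gender = seq$gender, fps = seq$fps
    ),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

expected_header <- function() {
  c("t", as.vector(t(outer(canonical_joints(), AXES, paste, sep = "_"))))
}

#' Read a skeleton sequence from a CSV file
#'
#' Validates the header against the canonical 61-column layout, requires
#' strictly increasing timestamps, and rejects malformed rows with an error
#' naming the offending line. Metadata is restored from the
#' `<path>.meta.json` sidecar when present.
#'
#' @param path CSV path produced by [write_sequence()] (or conforming to its
#'   layout).
#' @return A [skeleton_sequence()].
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) {
    stop("skeleton file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("parse error in ", path, ": no frame rows (line 2 missing)", call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  exp <- expected_header()
  if (length(header) != length(exp) || any(header != exp)) {
    stop("parse error in ", path,
      ": line 1 header does not match the canonical joint-column layout",
      call. = FALSE
    )
  }
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(vals) != 61L)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", bad[1] + 1L,
      " has ", lengths(vals)[bad[1]], " fields (expected 61)",
      call. = FALSE
    )
  }
  num <- matrix(
    suppressWarnings(as.numeric(unlist(vals, use.names = FALSE))),
    nrow = length(vals), ncol = 61L, byrow = TRUE
  )
  if (anyNA(num)) {
    bad_row <- which(apply(is.na(num), 1, any))[1]
    stop("parse error in ", path, ": line ", bad_row + 1L,
      " contains a non-numeric field",
      call. = FALSE
    )
  }
  tvec <- num[, 1]
  if (length(tvec) > 1 && any(diff(tvec) <= 0)) {
    stop("parse error in ", path, ": timestamps not strictly increasing",
      call. = FALSE
    )
  }
  pos <- array(num[, -1, drop = FALSE], dim = c(nrow(num), 3L, 20L))
  pos <- aperm(pos, c(1, 3, 2))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  skeleton_sequence(
    timestamps = tvec, positions = pos,
    subject_id = meta$subject_id %||% NA_character_,
    session_id = as.character(meta$session_id %||% NA_character_),
    gender = meta$gender %||% NA_character_,
    fps = meta$fps %||% (1 / stats::median(diff(tvec)))
  )
}

#' Generate a cohort's sessions to disk with a manifest
#'
#' Runs [generate_walk()] for every (subject, session) of a cohort and
#' writes one skeleton CSV per session plus a `manifest.csv` with columns
#' `subject_id, session_id, gender, path`. Session seeds are derived
#' deterministically from the cohort seed.
#'
#' @param cohort A [sample_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Tibble manifest, invisibly; also written to `dir/manifest.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(cohort$subjects)) {
    p <- cohort$subjects[[i]]
    for (s in seq_len(cohort$sessions_per_subject)) {
      seq_ <- generate_walk(p,
        duration = cohort$session_duration, fps = cohort$fps,
        seed = (cohort$seed * 10007L + i * 101L + s) %% .Machine$integer.max,
        session_id = as.character(s)
      )
      fn <- file.path(dir, sprintf("%s_s%d.csv", p$subject_id, s))
      write_sequence(seq_, fn)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = p$subject_id, session_id = as.character(s),
        gender = p$gender, path = fn
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset of skeleton sequences from a manifest
#'
#' Reads every session referenced by a `manifest.csv` (columns `subject_id,
#' session_id, gender, path`), preserving subject grouping so downstream
#' cross-validation can split by walker, never by session.
#'
#' @param manifest_path Path to the manifest CSV, or a data frame with the
#'   same columns.
#' @return A `gait_dataset`: list of records, each with `sequence`
#'   ([skeleton_sequence()]), `subject_id`, `session_id` and `gender`.
#' @export
load_dataset <- function(manifest_path) {
  manifest <- if (is.data.frame(manifest_path)) {
    manifest_path
  } else {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "session_id", "gender", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  missing <- !file.exists(manifest$path)
  if (any(missing)) {
    stop(
      "manifest rows reference missing files: ",
      paste(sprintf("row %d (%s)", which(missing), manifest$path[missing]),
        collapse = "; "
      ),
      call. = FALSE
    )
  }
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    list(
      sequence = read_sequence(manifest$path[i]),
      subject_id = as.character(manifest$subject_id[i]),
      session_id = as.character(manifest$session_id[i]),
      gender = as.character(manifest$gender[i])
    )
  })
  structure(records, class = "gait_dataset")
}

#' Build an in-memory dataset directly from a cohort
#'
#' Equivalent to [write_cohort()] followed by [load_dataset()] but without
#' touching disk; used by the experiment harness and tests.
#'
#' @param cohort A [sample_cohort()] result.
#' @param session_duration,fps Optional overrides of the cohort layout.
#' @return A `gait_dataset` (see [load_dataset()]).
#' @export
simulate_dataset <- function(cohort, session_duration = NULL, fps = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  dur <- session_duration %||% cohort$session_duration
  fps <- fps %||% cohort$fps
  records <- list()
  for (i in seq_along(cohort$subjects)) {
    p <- cohort$subjects[[i]]
    for (s in seq_len(cohort$sessions_per_subject)) {
      seq_ <- generate_walk(p,
        duration = dur, fps = fps,
        seed = (cohort$seed * 10007L + i * 101L + s) %% .Machine$integer.max,
        session_id = as.character(s)
      )
      records[[length(records) + 1L]] <- list(
        sequence = seq_, subject_id = p$subject_id,
        session_id = as.character(s), gender = p$gender
      )
    }
  }
  structure(records, class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  subj <- unique(vapply(x, `[[`, "", "subject_id"))
  cat(sprintf(
    "<gait_dataset> %d sequences from %d subjects\n",
    length(x), length(subj)
  ))
  invisible(x)
}
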