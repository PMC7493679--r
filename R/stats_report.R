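#' One-sample t-test of accuracies against chance
#'
#' Two-tailed one-sample t-test of per-replicate (or per-observer) accuracy
#' proportions against chance performance: `t = (mean - chance) / (s /
#' sqrt(n))` on `n - 1` degrees of freedom.
#'
#' @param accuracies Numeric vector of accuracy proportions, `n >= 2`.
#' @param chance Chance level (default 0.5 for binary classification).
#' @return A `gait_test` list: `statistic`, `df`, `p_value` (two-tailed),
#'   `mean`, `n`, `chance`, and a `zero_variance` flag (when all
#'   accuracies are identical the p-value is 1 at chance and 0 otherwise,
#'   by sign convention).
#' @export
ttest_vs_chance <- function(accuracies, chance = 0.5) {
  accuracies <- as.numeric(accuracies)
  n <- length(accuracies)
  if (n < 2) stop("need at least 2 accuracies", call. = FALSE)
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  zero_var <- s == 0
  if (zero_var) {
    statistic <- if (m == chance) 0 else sign(m - chance) * Inf
    p <- if (m == chance) 1 else 0
  } else {
    statistic <- (m - chance) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(statistic), df = n - 1)
  }
  structure(
    list(
      statistic = statistic, df = n - 1, p_value = p, mean = m, n = n,
      chance = chance, zero_variance = zero_var
    ),
    class = "gait_test"
  )
}

#' Variance-ratio F-test between two model cohorts
#'
#' Two-tailed variance-ratio test `F = s_A^2 / s_B^2` on `(n_A - 1,
#' n_B - 1)` degrees of freedom — the construction whose degrees of
#' freedom match cohort sizes minus one (e.g. 10 model replicates vs 21
#' observers gives df (9, 20)).
#'
#' @param group_a,group_b Numeric accuracy vectors, each `n >= 2`.
#' @return A `gait_test` list: `statistic`, `df` (length-2), `p_value`
#'   (two-tailed), group means and sizes, and a `zero_variance` flag
#'   (infinite F when the denominator variance is zero).
#' @export
ftest_between <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  zero_var <- vb == 0
  if (zero_var) {
    statistic <- if (va == 0) 1 else Inf
    p <- if (va == 0) 1 else 0
  } else {
    statistic <- va / vb
    pl <- stats::pf(statistic, length(a) - 1, length(b) - 1)
    p <- 2 * min(pl, 1 - pl)
  }
  structure(
    list(
      statistic = statistic, df = c(length(a) - 1, length(b) - 1),
      p_value = p, mean_a = mean(a), mean_b = mean(b),
      n_a = length(a), n_b = length(b), zero_variance = zero_var
    ),
    class = "gait_test"
  )
}

#' @export
print.gait_test <- function(x, ...) {
  if (length(x$df) == 2) {
    cat(sprintf("F(%d,%d) = %.4g, p = %.4g\n", x$df[1], x$df[2], x$statistic, x$p_value))
  } else {
    cat(sprintf("t(%d) = %.4g, p = %.4g\n", x$df, x$statistic, x$p_value))
  }
  invisible(x)
}

#' Per-replicate accuracies of a sweep
#'
#' Aggregates fold-level predictions to one accuracy per (family,
#' representation, window, replicate): total correct over total predicted,
#' the unit over which summary means and standard errors are taken.
#'
#' @param results A `sweep_result` from [run_experiment()].
#' @return Tibble with `family`, `representation`, `k`, `replicate`,
#'   `n_test`, `accuracy`.
#' @export
replicate_accuracy <- function(results) {
  results |>
    dplyr::group_by(.data$family, .data$representation, .data$k, .data$replicate) |>
    dplyr::summarise(
      n_test = sum(.data$n_test),
      accuracy = sum(.data$n_correct) / sum(.data$n_test),
      .groups = "drop"
    )
}

#' Summarize a sweep: mean accuracy and standard error per cell
#'
#' @param results A `sweep_result` from [run_experiment()].
#' @return Tibble with one row per (family, representation, k):
#'   `mean_accuracy`, `se` (over replicates; `NA` for a single
#'   replicate), `n_replicates`, `n_predictions`.
#' @export
summarize_sweep <- function(results) {
  if (!nrow(results)) stop("empty sweep results", call. = FALSE)
  replicate_accuracy(results) |>
    dplyr::group_by(.data$family, .data$representation, .data$k) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      se = if (dplyr::n() > 1) stats::sd(.data$accuracy) / sqrt(dplyr::n()) else NA_real_,
      n_replicates = dplyr::n(),
      n_predictions = sum(.data$n_test),
      .groups = "drop"
    )
}

#' Accuracy-versus-duration plot
#'
#' Mean accuracy per model family and representation as a function of the
#' window length (reported in frames and nominal seconds at the capture
#' rate), with a shaded band of plus/minus one standard error over
#' replicates and a dashed line at chance.
#'
#' @param summary Output of [summarize_sweep()].
#' @param fps Frame rate for the nominal duration axis (default 24).
#' @return A ggplot object.
#' @export
plot_accuracy_vs_duration <- function(summary, fps = 24) {
  df <- dplyr::filter(summary, !is.na(.data$k))
  df$duration <- 10 * df$k / fps
  df$model <- paste(df$family, df$representation, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(.data$duration, .data$mean_accuracy,
    color = .data$model, fill = .data$model
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_accuracy - .data$se,
        ymax = .data$mean_accuracy + .data$se
      ),
      alpha = 0.2, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey40") +
    ggplot2::labs(
      x = "Exposure duration (s)", y = "Mean accuracy",
      color = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Significance tests for a sweep, in long form
#'
#' For every (family, representation, k) cell: the two-tailed one-sample
#' t-test of replicate accuracies against chance.
#'
#' @param results A `sweep_result`.
#' @param chance Chance accuracy (default 0.5).
#' @return Tibble with the cell identifiers, `t`, `df`, `p_value`,
#'   `mean_accuracy`.
#' @export
sweep_tests <- function(results, chance = 0.5) {
  ra <- replicate_accuracy(results)
  ra |>
    dplyr::group_by(.data$family, .data$representation, .data$k) |>
    dplyr::summarise(
      t = if (dplyr::n() > 1) ttest_vs_chance(.data$accuracy, chance)$statistic else NA_real_,
      df = dplyr::n() - 1,
      p_value = if (dplyr::n() > 1) ttest_vs_chance(.data$accuracy, chance)$p_value else NA_real_,
      mean_accuracy = mean(.data$accuracy),
      .groups = "drop"
    )
}
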