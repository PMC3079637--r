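#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy single-mutant fitness estimates
#'
#' @param x A `qma_fit`.
#' @param ... Unused.
#' @return A tibble with columns `side` (`"query"` / `"array"`), `id`, and
#'   `estimate` (fitness units; `NA` where undefined).
#' @method tidy qma_fit
#' @export
tidy.qma_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(side = "query", id = names(x$x), estimate = unname(x$x)),
    tibble::tibble(side = "array", id = names(x$y), estimate = unname(x$y))
  )
}

#' One-row summary of a QMA fit
#'
#' @param x A `qma_fit`.
#' @param ... Unused.
#' @return A tibble with the quantile levels, sweep count, convergence flag
#'   and the numbers of defined estimates.
#' @method glance qma_fit
#' @export
glance.qma_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, n = x$n, p = x$p, q = x$q,
    iterations_run = x$iterations_run, converged = x$converged,
    n_defined_x = sum(!is.na(x$x)), n_defined_y = sum(!is.na(x$y)),
    median_x = stats::median(x$x, na.rm = TRUE),
    median_y = stats::median(x$y, na.rm = TRUE)
  )
}

#' Score distribution plot for a score matrix
#'
#' Histogram of the defined interaction scores with the extreme-tail
#' thresholds marked; the long tails beyond the dotted lines are the
#' candidate interactions.
#'
#' @param sm A `score_matrix`.
#' @param tail_fraction Tail probability per side (default 0.03).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(sm, tail_fraction = 0.03) {
  long <- as_tibble.fitness_matrix(sm)
  long <- long[!is.na(long$value), ]
  lo <- stats::quantile(long$value, tail_fraction, type = 7)
  hi <- stats::quantile(long$value, 1 - tail_fraction, type = 7)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(lo, hi), linetype = "dotted") +
    ggplot2::labs(
      x = "interaction score", y = "pairs",
      title = sprintf("Score distribution with %g%% tails", 100 * tail_fraction)
    )
}

#' Rank-rank scatter plot between two screens
#'
#' The rank-space analogue of the cross-screen scatter plot: each shared
#' pair is placed at its rank in screen A against its rank in screen B,
#' optionally coloured by reference interaction class.
#'
#' @param pairs A `pair_intersection` (see [intersect_datasets()]).
#' @param labels Optional character vector aligned with `pairs` rows (e.g.
#'   `"positive"`, `"negative"`, `"none"`) used for colouring.
#' @return A ggplot object.
#' @export
plot_rank_scatter <- function(pairs, labels = NULL) {
  df <- tibble::tibble(
    rank_a = rank(-pairs$value_a, ties.method = "average"),
    rank_b = rank(-pairs$value_b, ties.method = "average")
  )
  if (!is.null(labels)) {
    df$class <- labels
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$rank_a, y = .data$rank_b, colour = .data$class
    ))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_a, y = .data$rank_b))
  }
  p + ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "rank in screen A", y = "rank in screen B")
}
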