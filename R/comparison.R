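#' Intersect two screens over shared mutant pairs
#'
#' Finds the (query, array) pairs measured, with defined values, in both
#' screens. Matching is oriented by default: queries match queries and
#' arrays match arrays by exact identifier. With `allow_transpose = TRUE`
#' (for symmetric screens where a pair may be deposited in either
#' orientation) a pair of `a` also matches its flipped orientation in `b`,
#' and when both orientations are defined in `b` their values are averaged,
#' consistent with the duplicate-mean rule.
#'
#' @param a,b `fitness_matrix` or `score_matrix` objects.
#' @param allow_transpose Match flipped orientations in `b` (default
#'   `FALSE`).
#' @return A tibble of class `pair_intersection` with columns `query`,
#'   `array`, `value_a`, `value_b`; attributes `shared_query_ids`,
#'   `shared_array_ids`. An empty intersection gives a zero-row tibble.
#' @export
intersect_datasets <- function(a, b, allow_transpose = FALSE) {
  qs <- intersect(rownames(a), rownames(b))
  as <- intersect(colnames(a), colnames(b))
  va <- unclass(a)
  vb <- unclass(b)
  if (length(qs) > 0 && length(as) > 0) {
    grid_q <- rep(qs, times = length(as))
    grid_a <- rep(as, each = length(qs))
    value_a <- va[cbind(match(grid_q, rownames(a)), match(grid_a, colnames(a)))]
    value_b <- vb[cbind(match(grid_q, rownames(b)), match(grid_a, colnames(b)))]
  } else {
    grid_q <- grid_a <- character(0)
    value_a <- value_b <- numeric(0)
  }
  if (allow_transpose) {
    # also reachable: pairs of `a` whose flipped orientation exists in b
    qs2 <- intersect(rownames(a), colnames(b))
    as2 <- intersect(colnames(a), rownames(b))
    if (length(qs2) > 0 && length(as2) > 0) {
      g2q <- rep(qs2, times = length(as2))
      g2a <- rep(as2, each = length(qs2))
      v2a <- va[cbind(match(g2q, rownames(a)), match(g2a, colnames(a)))]
      v2b <- vb[cbind(match(g2a, rownames(b)), match(g2q, colnames(b)))]
      key1 <- paste(grid_q, grid_a, sep = "\r")
      key2 <- paste(g2q, g2a, sep = "\r")
      hit <- match(key2, key1)
      new <- is.na(hit)
      # average the two orientations of b where both are defined
      old <- which(!new)
      if (length(old) > 0) {
        i <- hit[old]
        value_b[i] <- rowMeans(cbind(value_b[i], v2b[old]), na.rm = TRUE)
        value_b[i][is.nan(value_b[i])] <- NA_real_
      }
      grid_q <- c(grid_q, g2q[new])
      grid_a <- c(grid_a, g2a[new])
      value_a <- c(value_a, v2a[new])
      value_b <- c(value_b, v2b[new])
    }
  }
  keep <- !is.na(value_a) & !is.na(value_b)
  out <- tibble::tibble(
    query = grid_q[keep], array = grid_a[keep],
    value_a = value_a[keep], value_b = value_b[keep]
  )
  out <- out[order(out$query, out$array), ]
  if (nrow(out) == 0) {
    message("intersection of '", attr(a, "name"), "' and '", attr(b, "name"),
      "' is empty")
  }
  attr(out, "shared_query_ids") <- qs
  attr(out, "shared_array_ids") <- as
  class(out) <- c("pair_intersection", class(out))
  out
}

#' Pearson and Spearman correlation over shared pairs
#'
#' Computes both coefficients over complete cases of two paired value
#' vectors. Spearman uses average ranks for ties. With fewer than three
#' complete pairs, or zero variance in either vector, the coefficients are
#' undefined and flagged rather than raised as an error.
#'
#' @param a_values,b_values Paired numeric vectors (e.g. `value_a` and
#'   `value_b` of a [intersect_datasets()] result).
#' @return A one-row tibble with `pearson`, `spearman`, `n_pairs`, `ok`.
#' @export
correlations <- function(a_values, b_values) {
  ok_idx <- !is.na(a_values) & !is.na(b_values)
  a <- a_values[ok_idx]
  b <- b_values[ok_idx]
  n <- length(a)
  degenerate <- n < 3 || stats::sd(a) == 0 || stats::sd(b) == 0
  if (degenerate) {
    return(tibble::tibble(
      pearson = NA_real_, spearman = NA_real_, n_pairs = n, ok = FALSE
    ))
  }
  tibble::tibble(
    pearson = stats::cor(a, b, method = "pearson"),
    spearman = stats::cor(a, b, method = "spearman"),
    n_pairs = n, ok = TRUE
  )
}

#' Extreme-tail agreement between two screens as a ROC AUC
#'
#' Measures how well one screen's scores predict the other screen's most
#' extreme pairs: the reference screen's extreme tail (via [call_extremes()]
#' on the shared pairs) defines the positive labels, the predictor's values
#' are used as the ranking (negated for the negative tail so that stronger
#' aggravating evidence ranks first), and the ROC AUC summarizes the
#' agreement.
#'
#' @param reference,predictor `score_matrix` objects.
#' @param pairs A `pair_intersection` of the two (reference as `a`).
#' @param tail_fraction Tail probability defining the reference extreme
#'   (default 0.03).
#' @param tail `"positive"` or `"negative"` — which extreme of the
#'   reference to predict.
#' @return A one-row tibble with `auc`, `n_tail`, `n_pairs`, `ok`; `ok` is
#'   `FALSE` (and `auc` `NA`) when the reference tail is empty.
#' @export
extreme_agreement_auc <- function(reference, predictor, pairs,
                                  tail_fraction = 0.03,
                                  tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must lie strictly between 0 and 0.5", call. = FALSE)
  }
  ref <- pairs$value_a
  prd <- pairs$value_b
  n <- length(ref)
  if (n == 0) {
    return(tibble::tibble(auc = NA_real_, n_tail = 0L, n_pairs = 0L, ok = FALSE))
  }
  lo <- unname(stats::quantile(ref, tail_fraction, type = 7))
  hi <- unname(stats::quantile(ref, 1 - tail_fraction, type = 7))
  labels <- if (tail == "positive") {
    as.integer(ref >= hi & !(ref <= lo))
  } else {
    as.integer(ref <= lo & !(ref >= hi))
  }
  if (sum(labels) == 0 || sum(labels) == n) {
    return(tibble::tibble(
      auc = NA_real_, n_tail = sum(labels), n_pairs = n, ok = FALSE
    ))
  }
  scores <- if (tail == "positive") prd else -prd
  roc <- roc_curve(scores, labels)
  tibble::tibble(auc = roc$auc, n_tail = roc$n_pos, n_pairs = n, ok = TRUE)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `found` interactions in a cell of `t`
#' pairs drawn from a universe of `K` pairs containing `M` interactions,
#' under random placement. Clamped to the interval `[1e-100, 0.99]` used
#' for display of enrichment grids, so a certain event (e.g. `found = 0`)
#' reports 0.99 and extreme enrichments never underflow past 1e-100.
#'
#' @param K Total pairs in the universe.
#' @param M Total interactions of the class (`0 <= M <= K`).
#' @param t Pairs in the cell (`t <= K`).
#' @param found Interactions observed in the cell (`0 <= found <= t`).
#' @return The clamped upper-tail p-value.
#' @examples
#' hypergeom_upper(10, 4, 3, 2) # exact value 1/3
#' @export
hypergeom_upper <- function(K, M, t, found) {
  if (M < 0 || M > K || t < 0 || t > K || found < 0 || found > t) {
    stop("require 0 <= M <= K, 0 <= found <= t <= K", call. = FALSE)
  }
  p <- stats::phyper(found - 1, M, K - M, t, lower.tail = FALSE)
  min(max(p, 1e-100), 0.99)
}

#' Rank-grid enrichment of reference interactions
#'
#' Reproduces the grid overlay of a rank-rank scatter plot between two
#' screens: each axis is split into `grid_dim` equal-count rank bins and,
#' for every cell of the resulting grid, an upper-tail hypergeometric test
#' measures whether known positive (and, separately, negative) interactions
#' are enriched among the pairs in that cell relative to random placement.
#' Bin boundaries are rank quantiles; a pair exactly on a boundary goes to
#' the lower bin.
#'
#' @param a_ranks,b_ranks Paired rank vectors (rank 1 = strongest evidence)
#'   for the shared pairs in the two screens.
#' @param positive_labels,negative_labels Binary vectors (1 = known
#'   interaction of that class), aligned with the ranks.
#' @param grid_dim Cells per axis (default 6).
#' @return An object of class `enrichment_grid`: list with matrices
#'   `positive_p`, `negative_p`, `counts` (pairs per cell), `positive_found`,
#'   `negative_found`, and the bin boundaries.
#' @export
enrichment_grid <- function(a_ranks, b_ranks, positive_labels, negative_labels,
                            grid_dim = 6) {
  if (grid_dim < 2) stop("grid_dim must be >= 2", call. = FALSE)
  n <- length(a_ranks)
  if (length(b_ranks) != n || length(positive_labels) != n ||
    length(negative_labels) != n) {
    stop("rank and label vectors must be aligned", call. = FALSE)
  }
  if (n < grid_dim^2) {
    stop("fewer pairs than grid cells", call. = FALSE)
  }
  bin_a <- rank_bins(a_ranks, grid_dim)
  bin_b <- rank_bins(b_ranks, grid_dim)
  counts <- matrix(0L, grid_dim, grid_dim)
  pos_found <- matrix(0L, grid_dim, grid_dim)
  neg_found <- matrix(0L, grid_dim, grid_dim)
  for (i in seq_len(n)) {
    counts[bin_a[i], bin_b[i]] <- counts[bin_a[i], bin_b[i]] + 1L
    pos_found[bin_a[i], bin_b[i]] <- pos_found[bin_a[i], bin_b[i]] + positive_labels[i]
    neg_found[bin_a[i], bin_b[i]] <- neg_found[bin_a[i], bin_b[i]] + negative_labels[i]
  }
  M_pos <- sum(positive_labels)
  M_neg <- sum(negative_labels)
  pos_p <- neg_p <- matrix(NA_real_, grid_dim, grid_dim)
  for (i in seq_len(grid_dim)) {
    for (j in seq_len(grid_dim)) {
      pos_p[i, j] <- hypergeom_upper(n, M_pos, counts[i, j], pos_found[i, j])
      neg_p[i, j] <- hypergeom_upper(n, M_neg, counts[i, j], neg_found[i, j])
    }
  }
  structure(
    list(
      grid_dim = grid_dim, counts = counts,
      positive_p = pos_p, negative_p = neg_p,
      positive_found = pos_found, negative_found = neg_found,
      positive_total = M_pos, negative_total = M_neg, n_pairs = n,
      a_bounds = attr(bin_a, "bounds"), b_bounds = attr(bin_b, "bounds")
    ),
    class = "enrichment_grid"
  )
}

# equal-count bins over ranks; boundary values fall into the lower bin
rank_bins <- function(r, k) {
  breaks <- stats::quantile(r, probs = seq(0, 1, length.out = k + 1), type = 7)
  bins <- findInterval(r, breaks, left.open = TRUE, rightmost.closed = TRUE)
  bins[bins < 1L] <- 1L
  bins[bins > k] <- k
  structure(as.integer(bins), bounds = unname(breaks))
}

#' @export
print.enrichment_grid <- function(x, ...) {
  cat(sprintf(
    "<enrichment_grid> %d x %d over %d pairs (%d positive, %d negative interactions)\n",
    x$grid_dim, x$grid_dim, x$n_pairs, x$positive_total, x$negative_total
  ))
  cat("min positive p:", format(min(x$positive_p), digits = 3),
    "| min negative p:", format(min(x$negative_p), digits = 3), "\n")
  invisible(x)
}

#' Tidy an enrichment grid into long format
#' @param x An `enrichment_grid`.
#' @param ... Unused.
#' @return A tibble with one row per (cell, class): columns `bin_a`,
#'   `bin_b`, `class`, `p_value`, `found`, `cell_size`.
#' @method tidy enrichment_grid
#' @export
tidy.enrichment_grid <- function(x, ...) {
  k <- x$grid_dim
  cells <- expand.grid(bin_a = seq_len(k), bin_b = seq_len(k))
  dplyr::bind_rows(
    tibble::tibble(
      bin_a = cells$bin_a, bin_b = cells$bin_b, class = "positive",
      p_value = x$positive_p[as.matrix(cells)],
      found = x$positive_found[as.matrix(cells)],
      cell_size = x$counts[as.matrix(cells)]
    ),
    tibble::tibble(
      bin_a = cells$bin_a, bin_b = cells$bin_b, class = "negative",
      p_value = x$negative_p[as.matrix(cells)],
      found = x$negative_found[as.matrix(cells)],
      cell_size = x$counts[as.matrix(cells)]
    )
  )
}

#' Plot an enrichment grid
#' @param object An `enrichment_grid`.
#' @param ... Unused.
#' @return A ggplot object: tiles coloured by -log10 p per class.
#' @method autoplot enrichment_grid
#' @export
autoplot.enrichment_grid <- function(object, ...) {
  df <- tidy.enrichment_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_b, y = .data$bin_a,
    fill = -log10(.data$p_value)
  )) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "rank bin (screen B)", y = "rank bin (screen A)",
      fill = "-log10 p"
    )
}
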