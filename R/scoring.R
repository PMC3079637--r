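#' Score genetic interactions as residuals from a null model
#'
#' Transforms a double-mutant fitness matrix into an interaction score
#' matrix `s[a, b] = w[a, b] - s(x[a], y[b])`. A large positive score is
#' evidence for an alleviating (positive) interaction, a large negative
#' score for an aggravating (negative) interaction — the extreme case being
#' synthetic lethality, `w[a, b] = 0`, which under the product null scores
#' `-x[a] * y[b]`. Scores near zero indicate non-interacting pairs.
#'
#' For `null_fn = "scaled_epistasis"` the product residual is divided by a
#' sign-dependent normalizer: the distance from the product expectation to
#' the masking bound `min(x[a], y[b])` for positive residuals, and the
#' distance to lethality (`x[a] * y[b]` itself) for negative residuals, so
#' scores land on a roughly comparable `[-1, 1]`-like scale across pairs.
#' The normalizer is floored at `1e-8`.
#'
#' @param fm A `fitness_matrix`.
#' @param est A `qma_fit` with dimensions matching `fm` (see
#'   [qma_estimate()]).
#' @param null_fn One of `"product"`, `"minimum"`, `"maximum"`,
#'   `"scaled_epistasis"`.
#' @return A `score_matrix`; cells are `NA` wherever the fitness value or
#'   either single-mutant estimate is undefined.
#' @export
score_interactions <- function(fm, est, null_fn = "product") {
  null_fn <- match.arg(null_fn, c("product", "minimum", "maximum", "scaled_epistasis"))
  W <- unclass(fm)
  if (est$m != nrow(W) || est$n != ncol(W)) {
    stop(sprintf(
      "estimate dimensions (%d x %d) do not match matrix (%d x %d)",
      est$m, est$n, nrow(W), ncol(W)
    ), call. = FALSE)
  }
  base_fn <- if (null_fn == "scaled_epistasis") "product" else null_fn
  E <- expected_fitness(est, base_fn)
  S <- W - E
  if (null_fn == "scaled_epistasis") {
    bound <- outer(est$x, est$y, pmin)
    d_pos <- pmax(abs(bound - E), 1e-8)
    d_neg <- pmax(E, 1e-8)
    S <- ifelse(S >= 0, S / d_pos, S / d_neg)
  }
  score_matrix(S,
    query_ids = rownames(W), array_ids = colnames(W),
    name = paste0(attr(fm, "name"), "_scores"), null_fn = null_fn,
    provenance = list(
      p = est$p, q = est$q, iterations = est$iterations_run,
      min_obs = est$min_obs
    )
  )
}

#' Median-estimate baseline interaction score
#'
#' The baseline scoring scheme: single-mutant effects estimated with medians
#' (`p = q = 0.5`) in a single two-pass sweep, scored with the product null.
#' Identical, cell for cell, to
#' `score_interactions(fm, qma_estimate(fm, 0.5, 0.5, max_iter = 1), "product")`.
#'
#' @param fm A `fitness_matrix`.
#' @param min_obs Passed to [qma_estimate()].
#' @return A `score_matrix`.
#' @export
median_baseline_score <- function(fm, min_obs = 5) {
  est <- qma_estimate(fm, p = 0.5, q = 0.5, max_iter = 1, min_obs = min_obs)
  score_interactions(fm, est, "product")
}

#' Call extreme-tail candidate interactions
#'
#' Returns the pairs whose scores lie in the two extreme tails of the score
#' distribution: at or above the `1 - tail_fraction` quantile (candidate
#' positive interactions) and at or below the `tail_fraction` quantile
#' (candidate negatives). The default 3% per tail follows the empirical
#' interaction-rate estimate from unbiased screens (about 3.15%).
#'
#' Pairs exactly at a quantile boundary are included in the tail. When the
#' two thresholds coincide (e.g. all scores equal) any pair falling in both
#' tails is ambiguous and dropped from both, so a constant score matrix
#' yields no calls.
#'
#' @param sm A `score_matrix`.
#' @param tail_fraction Tail probability per side, in `(0, 0.5)`.
#' @return A list with tibbles `positive` and `negative` (columns `query`,
#'   `array`, `score`), each sorted by decreasing absolute score, plus the
#'   thresholds used.
#' @export
call_extremes <- function(sm, tail_fraction = 0.03) {
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must lie strictly between 0 and 0.5", call. = FALSE)
  }
  long <- as_tibble.fitness_matrix(sm)
  long <- long[!is.na(long$value), ]
  if (nrow(long) == 0) {
    stop("no defined scores to call extremes from", call. = FALSE)
  }
  lo <- unname(stats::quantile(long$value, tail_fraction, type = 7))
  hi <- unname(stats::quantile(long$value, 1 - tail_fraction, type = 7))
  in_pos <- long$value >= hi
  in_neg <- long$value <= lo
  both <- in_pos & in_neg
  pos <- long[in_pos & !both, ]
  neg <- long[in_neg & !both, ]
  pos <- pos[order(-pos$value, pos$query, pos$array), ]
  neg <- neg[order(neg$value, neg$query, neg$array), ]
  list(
    positive = dplyr::rename(tibble::as_tibble(pos), score = "value"),
    negative = dplyr::rename(tibble::as_tibble(neg), score = "value"),
    lower_threshold = lo,
    upper_threshold = hi,
    tail_fraction = tail_fraction
  )
}
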