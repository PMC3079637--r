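#' Rank mutant pairs by interaction score within one screen
#'
#' Ranks a set of pairs by the evidence their score provides for a given
#' interaction direction. For `direction = "positive"` the most positive
#' score receives rank 1; for `"negative"` the most negative score does.
#' Ties receive average ranks. Pairs whose score is undefined are dropped;
#' the returned tibble's `index` column maps surviving rows back to the
#' positions in the requested pair list.
#'
#' @param sm A `score_matrix`.
#' @param pairs A data frame (or tibble) with columns `query` and `array`
#'   naming pairs defined in `sm`. Defaults to every cell of `sm`.
#' @param direction `"positive"` or `"negative"`.
#' @return A tibble of class `ranked_pairs` with columns `index`, `query`,
#'   `array`, `score`, `rank`, and attributes `direction` and `source`.
#' @export
rank_pairs <- function(sm, pairs = NULL, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (is.null(pairs)) {
    pairs <- expand.grid(
      query = rownames(sm), array = colnames(sm),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
  }
  if (nrow(pairs) == 0) stop("empty pair list", call. = FALSE)
  ri <- match(pairs$query, rownames(sm))
  ci <- match(pairs$array, colnames(sm))
  if (anyNA(ri) || anyNA(ci)) {
    stop("some pairs reference strains absent from the score matrix", call. = FALSE)
  }
  s <- unclass(sm)[cbind(ri, ci)]
  keep <- !is.na(s)
  out <- tibble::tibble(
    index = which(keep),
    query = pairs$query[keep],
    array = pairs$array[keep],
    score = s[keep]
  )
  key <- if (direction == "positive") -out$score else out$score
  out$rank <- rank(key, ties.method = "average")
  attr(out, "direction") <- direction
  attr(out, "source") <- attr(sm, "name")
  class(out) <- c("ranked_pairs", class(out))
  out
}

#' Aggregate pair rankings across screens
#'
#' Combines two or more per-screen rankings of the same mutant pairs into a
#' single consensus ordering using one of four aggregation functions:
#' minimum of the ranks (liberal), maximum of the ranks (conservative),
#' product of the ranks, or the Borda count (sum of the ranks). Smaller
#' aggregate values indicate stronger combined evidence; the output is
#' ordered ascending by aggregate value with ties broken lexicographically
#' by pair identifier for reproducibility.
#'
#' Only pairs ranked in every input are aggregated, and the inputs are
#' expected to be ranked over the same shared pair set so their rank scales
#' are comparable.
#'
#' @param rankings A list of `ranked_pairs` tibbles (see [rank_pairs()]),
#'   all with the same `direction`.
#' @param method One of `"minimum"`, `"maximum"`, `"product"`, `"borda"`.
#' @return A tibble of class `aggregated_ranking` with columns `query`,
#'   `array`, one `rank_<i>` column per input, `aggregate`, `final_rank`.
#' @examples
#' # two screens ranking three pairs; Borda sums 4, 3, 5 put P2 first
#' @export
aggregate_ranks <- function(rankings, method = c("borda", "product", "minimum", "maximum")) {
  method <- match.arg(method)
  if (!is.list(rankings) || length(rankings) < 2) {
    stop("need at least two rankings to aggregate", call. = FALSE)
  }
  dirs <- vapply(rankings, function(r) attr(r, "direction") %||% NA_character_, character(1))
  if (length(unique(dirs)) != 1) {
    stop("all rankings must share the same direction", call. = FALSE)
  }
  keys <- lapply(rankings, function(r) paste(r$query, r$array, sep = "\r"))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) {
    stop("rankings have no pairs in common", call. = FALSE)
  }
  rank_cols <- lapply(seq_along(rankings), function(i) {
    rankings[[i]]$rank[match(common, keys[[i]])]
  })
  R <- do.call(cbind, rank_cols)
  agg <- switch(method,
    minimum = apply(R, 1, min),
    maximum = apply(R, 1, max),
    product = apply(R, 1, prod),
    borda = rowSums(R)
  )
  qa <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  out <- tibble::tibble(query = qa[, 1], array = qa[, 2])
  for (i in seq_along(rank_cols)) out[[paste0("rank_", i)]] <- rank_cols[[i]]
  out$aggregate <- agg
  out <- out[order(out$aggregate, out$query, out$array), ]
  out$final_rank <- seq_len(nrow(out))
  attr(out, "method") <- method
  attr(out, "direction") <- dirs[1]
  class(out) <- c("aggregated_ranking", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
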