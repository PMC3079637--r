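#' Construct a double-mutant fitness matrix
#'
#' A fitness matrix holds quantitative double-mutant fitness values
#' `w[a, b]` for `m` query strains (rows) crossed against `n` array strains
#' (columns). Values are non-negative on the fitness scale of the screen
#' (typically normalized so the median is close to 1); a value of 0 encodes
#' lethality of the double mutant, and `NA` encodes a missing measurement.
#'
#' @param values Numeric matrix of fitness values (`NA` allowed, all present
#'   values must be `>= 0`).
#' @param query_ids Character vector of row (query strain) identifiers.
#'   Defaults to `rownames(values)`.
#' @param array_ids Character vector of column (array strain) identifiers.
#'   Defaults to `colnames(values)`.
#' @param name Free-text label for the dataset.
#'
#' @return An object of class `fitness_matrix`: a numeric matrix with
#'   `dimnames` set to the strain identifiers and a `name` attribute.
#' @examples
#' fm <- fitness_matrix(matrix(c(1, 0.5, 0.8, 0.4), 2, 2),
#'   query_ids = c("qA", "qB"), array_ids = c("aA", "aB")
#' )
#' fm
#' @export
fitness_matrix <- function(values, query_ids = rownames(values),
                           array_ids = colnames(values), name = "screen") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(query_ids)) query_ids <- paste0("q", seq_len(nrow(values)))
  if (is.null(array_ids)) array_ids <- paste0("a", seq_len(ncol(values)))
  if (length(query_ids) != nrow(values) || length(array_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  bad <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "negative fitness value at query '%s', array '%s'",
      query_ids[bad[1, 1]], array_ids[bad[1, 2]]
    ), call. = FALSE)
  }
  dimnames(values) <- list(as.character(query_ids), as.character(array_ids))
  structure(values, name = name, class = c("fitness_matrix", "matrix", "array"))
}

#' Construct an interaction score matrix
#'
#' A score matrix holds signed interaction residuals `s[a, b]` aligned with a
#' fitness matrix: positive scores mark candidate alleviating (positive)
#' interactions, negative scores candidate aggravating (negative)
#' interactions, and scores near zero non-interacting pairs.
#'
#' @param values Numeric matrix of residual scores (`NA` allowed, any sign).
#' @inheritParams fitness_matrix
#' @param null_fn Name of the null scoring function the residuals were
#'   computed under.
#' @param provenance Optional list of estimation parameters (quantile levels,
#'   iterations) recorded for reproducibility.
#'
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, query_ids = rownames(values),
                         array_ids = colnames(values), name = "scores",
                         null_fn = "product", provenance = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(query_ids)) query_ids <- paste0("q", seq_len(nrow(values)))
  if (is.null(array_ids)) array_ids <- paste0("a", seq_len(ncol(values)))
  if (length(query_ids) != nrow(values) || length(array_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(values) <- list(as.character(query_ids), as.character(array_ids))
  structure(values,
    name = name, null_fn = null_fn, provenance = provenance,
    class = c("score_matrix", "matrix", "array")
  )
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat(sprintf(
    "<fitness_matrix '%s'> %d queries x %d arrays (%d missing)\n",
    attr(x, "name"), nrow(x), ncol(x), sum(is.na(x))
  ))
  k <- min(5L, nrow(x))
  l <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE])
  invisible(x)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "<score_matrix '%s'> %d queries x %d arrays, null = %s (%d missing)\n",
    attr(x, "name"), nrow(x), ncol(x), attr(x, "null_fn"), sum(is.na(x))
  ))
  k <- min(5L, nrow(x))
  l <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(l), drop = FALSE])
  invisible(x)
}

#' Query strain identifiers of a screen matrix
#' @param x A `fitness_matrix` or `score_matrix`.
#' @return Character vector of row (query) identifiers.
#' @export
query_ids <- function(x) rownames(x)

#' Array strain identifiers of a screen matrix
#' @param x A `fitness_matrix` or `score_matrix`.
#' @return Character vector of column (array) identifiers.
#' @export
array_ids <- function(x) colnames(x)

#' Convert a screen matrix to a long tibble
#'
#' @param x A `fitness_matrix` or `score_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `query`, `array`, `value`; missing cells are
#'   kept as `NA` rows.
#' @method as_tibble fitness_matrix
#' @export
as_tibble.fitness_matrix <- function(x, ...) {
  tibble::tibble(
    query = rep(rownames(x), times = ncol(x)),
    array = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' @rdname as_tibble.fitness_matrix
#' @method as_tibble score_matrix
#' @export
as_tibble.score_matrix <- function(x, ...) as_tibble.fitness_matrix(x, ...)

#' Merge duplicate query and array strains by averaging
#'
#' Rows sharing a query identifier are replaced by a single row of
#' element-wise means over the present values (missing entries are ignored;
#' a cell that is missing in every duplicate stays missing), and likewise for
#' columns sharing an array identifier. Output order is the order of first
#' occurrence. Averaging ignores missing values rather than treating them as
#' zero, because fitness 0 is a biological measurement (lethality), not an
#' absent one.
#'
#' @param fm A `fitness_matrix` (or `score_matrix`).
#' @return A matrix of the same class with unique identifiers.
#' @examples
#' fm <- fitness_matrix(rbind(c(1, 2), c(3, 4)),
#'   query_ids = c("gA", "gA"), array_ids = c("a1", "a2")
#' )
#' merge_duplicates(fm) # single row (2, 3)
#' @export
merge_duplicates <- function(fm) {
  v <- unclass(fm)
  v <- merge_dim(v, 1L)
  v <- merge_dim(v, 2L)
  if (inherits(fm, "score_matrix")) {
    score_matrix(v,
      name = attr(fm, "name"), null_fn = attr(fm, "null_fn"),
      provenance = attr(fm, "provenance")
    )
  } else {
    fitness_matrix(v, name = attr(fm, "name"))
  }
}

# mean over duplicate rows (margin 1) or columns (margin 2), NAs ignored
merge_dim <- function(v, margin) {
  ids <- dimnames(v)[[margin]]
  if (!anyDuplicated(ids)) {
    return(v)
  }
  keep <- unique(ids)
  f <- factor(ids, levels = keep)
  if (margin == 2L) v <- t(v)
  sums <- rowsum(ifelse(is.na(v), 0, v), f)
  cnts <- rowsum((!is.na(v)) * 1, f)
  out <- sums / cnts # 0/0 -> NaN where all duplicates missing
  out[cnts == 0] <- NA_real_
  rownames(out) <- keep
  if (margin == 2L) out <- t(out)
  out
}
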