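# Shared fixtures and independent oracles for the test suite.

# strictly positive rank-one screen
rank_one_fm <- function(x = c(1.0, 0.5, 0.9), y = c(1.0, 0.8, 0.6)) {
  fitness_matrix(outer(x, y),
    query_ids = sprintf("q%d", seq_along(x)),
    array_ids = sprintf("a%d", seq_along(y)),
    name = "rank_one"
  )
}

# the rank-one screen with one cell forced lethal (w[2, 2] = 0)
planted_lethal_fm <- function() {
  W <- outer(c(1.0, 0.5, 0.9), c(1.0, 0.8, 0.6))
  W[2, 2] <- 0
  fitness_matrix(W,
    query_ids = c("q1", "q2", "q3"),
    array_ids = c("a1", "a2", "a3"), name = "lethal"
  )
}

# wrap known single-mutant vectors as a fit object, bypassing estimation
fake_fit <- function(x, y, p = 0.5, q = 0.5) {
  structure(
    list(
      x = x, y = y, p = p, q = q, iterations_run = 0L, converged = TRUE,
      max_iter = 1L, tol = 0, min_obs = 1L, m = length(x), n = length(y)
    ),
    class = "qma_fit"
  )
}

# brute-force Mann-Whitney AUC: fraction of concordant positive/negative
# pairs, ties counted one half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# upper-tail hypergeometric probability by exhaustive enumeration of all
# C(K, t) draws, successes being the first M items
hyper_oracle_tail <- function(K, M, t, found) {
  if (t == 0) {
    return(as.numeric(found == 0))
  }
  draws <- utils::combn(K, t)
  hits <- colSums(draws <= M)
  mean(hits >= found)
}

# set-based reference-class oracle: label every cell of the universe from
# first principles (unordered pairs, ambiguity, exclusions, self pairs)
class_matrix_oracle <- function(edges, class_name, query_ids, array_ids,
                                category_map = default_category_map(),
                                exclude_edges = NULL) {
  unordered <- function(a, b) paste(pmin(a, b), pmax(a, b))
  in_class <- function(cls) {
    terms <- tolower(trimws(category_map[[cls]]))
    sel <- tolower(trimws(edges$category)) %in% terms
    unique(unordered(edges$gene_a[sel], edges$gene_b[sel]))
  }
  pos <- in_class("positive")
  neg <- in_class("negative")
  ambig <- intersect(pos, neg)
  mine <- if (class_name == "positive") pos else neg
  excl <- if (!is.null(exclude_edges)) {
    unique(unordered(exclude_edges$gene_a, exclude_edges$gene_b))
  } else {
    character(0)
  }
  out <- matrix("non_interacting", length(query_ids), length(array_ids),
    dimnames = list(query_ids, array_ids)
  )
  for (i in seq_along(query_ids)) {
    for (j in seq_along(array_ids)) {
      key <- unordered(query_ids[i], array_ids[j])
      if (key %in% mine) out[i, j] <- "interacting"
      if (key %in% ambig || key %in% excl) out[i, j] <- "excluded"
      if (query_ids[i] == array_ids[j]) out[i, j] <- "excluded"
    }
  }
  out
}

# noise-free generator settings used by exactness tests
noiseless_params <- function(...) {
  screen_params(
    noise_sd = 0, missing_fraction = 0, duplicate_fraction = 0,
    ...
  )
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
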