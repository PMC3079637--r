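#' Default category map for curated interaction classes
#'
#' Maps the experimental-system categories of curated genetic-interaction
#' databases to the positive (alleviating) and negative (aggravating)
#' interaction classes. Matching is case-insensitive after trimming, and
#' both the "Synthetic Lethality" and "Synthetic Lethal" spellings are
#' accepted.
#'
#' @return A named list with character vectors `positive` and `negative`.
#' @export
default_category_map <- function() {
  list(
    positive = c("Positive Genetic", "Phenotypic Suppression"),
    negative = c(
      "Negative Genetic", "Synthetic Growth Defect",
      "Synthetic Lethality", "Synthetic Lethal",
      "Phenotypic Enhancement"
    )
  )
}

norm_category <- function(x) tolower(trimws(x))

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Build a ternary reference interaction class matrix
#'
#' Labels every (query, array) pair in the given identifier universe as
#' `interacting`, `non_interacting` or `excluded` for one interaction class
#' (positive or negative), from a curated edge list. Gene pairs are treated
#' as unordered: an edge A-B also labels the reciprocal cell B-A
#' (symmetric closure). Pairs annotated in both the positive and the
#' negative class are ambiguous and are excluded here and must be excluded
#' in the sibling matrix too (pass the full edge list so both classes are
#' visible). Pairs in `exclude_edges` (also unordered) and self pairs are
#' excluded as well: a cell whose query and array are the same gene
#' measures a single mutant, not an interaction.
#'
#' @param edges A tibble of edges as returned by [read_edge_list()]
#'   (columns `gene_a`, `gene_b`, `category`).
#' @param class_name `"positive"` or `"negative"`.
#' @param query_ids,array_ids Identifier universe the matrix is built over.
#' @param category_map Named list mapping `positive` and `negative` to
#'   category terms; see [default_category_map()].
#' @param exclude_edges Optional tibble of edges (same columns) whose
#'   unordered pairs are excluded, e.g. interactions originating from the
#'   screens under evaluation.
#' @param strict If `TRUE`, an edge category missing from `category_map` is
#'   an error; otherwise such edges are ignored with a warning.
#' @return An object of class `interaction_class_matrix`: a character matrix
#'   of labels with attributes `class_name` and `categories_used`.
#' @export
build_class_matrix <- function(edges, class_name = c("positive", "negative"),
                               query_ids, array_ids,
                               category_map = default_category_map(),
                               exclude_edges = NULL, strict = FALSE) {
  class_name <- match.arg(class_name)
  pos_terms <- norm_category(category_map$positive)
  neg_terms <- norm_category(category_map$negative)
  cat_norm <- norm_category(edges$category)
  unknown <- !(cat_norm %in% c(pos_terms, neg_terms))
  if (any(unknown)) {
    msg <- sprintf(
      "%d edge(s) with unmapped category term(s): %s",
      sum(unknown), paste(unique(edges$category[unknown]), collapse = ", ")
    )
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  pos_pairs <- unique(pair_key(
    edges$gene_a[cat_norm %in% pos_terms],
    edges$gene_b[cat_norm %in% pos_terms]
  ))
  neg_pairs <- unique(pair_key(
    edges$gene_a[cat_norm %in% neg_terms],
    edges$gene_b[cat_norm %in% neg_terms]
  ))
  ambiguous <- intersect(pos_pairs, neg_pairs)
  class_pairs <- if (class_name == "positive") pos_pairs else neg_pairs
  excl_pairs <- if (!is.null(exclude_edges) && nrow(exclude_edges) > 0) {
    unique(pair_key(exclude_edges$gene_a, exclude_edges$gene_b))
  } else {
    character(0)
  }
  query_ids <- as.character(query_ids)
  array_ids <- as.character(array_ids)
  cell_key <- pair_key(
    rep(query_ids, times = length(array_ids)),
    rep(array_ids, each = length(query_ids))
  )
  lab <- ifelse(cell_key %in% class_pairs, "interacting", "non_interacting")
  lab[cell_key %in% ambiguous] <- "excluded"
  lab[cell_key %in% excl_pairs] <- "excluded"
  lab[rep(query_ids, times = length(array_ids)) ==
    rep(array_ids, each = length(query_ids))] <- "excluded"
  labels <- matrix(lab,
    nrow = length(query_ids),
    dimnames = list(query_ids, array_ids)
  )
  structure(labels,
    class_name = class_name,
    categories_used = category_map[[class_name]],
    class = c("interaction_class_matrix", "matrix", "array")
  )
}

#' @export
print.interaction_class_matrix <- function(x, ...) {
  tab <- table(factor(unclass(x),
    levels = c("interacting", "non_interacting", "excluded")
  ))
  cat(sprintf(
    "<interaction_class_matrix '%s'> %d x %d: %d interacting, %d non-interacting, %d excluded\n",
    attr(x, "class_name"), nrow(x), ncol(x),
    tab[["interacting"]], tab[["non_interacting"]], tab[["excluded"]]
  ))
  invisible(x)
}

#' Extract reference labels for a list of pairs
#'
#' Looks up the class labels of the requested (query, array) pairs in
#' request order, drops the excluded pairs, and returns an index map from
#' the surviving labels back to the request positions, so score vectors can
#' be subset consistently.
#'
#' @param cm An `interaction_class_matrix`.
#' @param pairs Data frame with columns `query` and `array`, all within the
#'   matrix universe.
#' @return A list with `labels` (character vector, values `interacting` /
#'   `non_interacting`), `index` (integer positions into `pairs`), and
#'   `binary` (1 for interacting, 0 otherwise) — ambiguous pairs never
#'   appear.
#' @export
restrict_labels <- function(cm, pairs) {
  ri <- match(pairs$query, rownames(cm))
  ci <- match(pairs$array, colnames(cm))
  if (anyNA(ri) || anyNA(ci)) {
    stop("some pairs fall outside the class matrix universe", call. = FALSE)
  }
  lab <- unclass(cm)[cbind(ri, ci)]
  keep <- lab != "excluded"
  list(
    labels = lab[keep],
    index = which(keep),
    binary = as.integer(lab[keep] == "interacting")
  )
}
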