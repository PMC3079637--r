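edges_tbl <- function(a, b, cat) {
  tibble::tibble(gene_a = a, gene_b = b, category = cat, source = "test")
}

test_that("unordered pairs are symmetrized across orientations", {
  edges <- edges_tbl("A", "B", "Positive Genetic")
  cm <- build_class_matrix(edges, "positive",
    query_ids = c("A", "B"), array_ids = c("A", "B")
  )
  expect_equal(unclass(cm)["A", "B"], "interacting")
  expect_equal(unclass(cm)["B", "A"], "interacting")
  expect_equal(unclass(cm)["A", "A"], "excluded") # self pair
})

test_that("pairs annotated in both classes are excluded from both matrices", {
  edges <- edges_tbl(
    c("A", "A"), c("B", "B"),
    c("Positive Genetic", "Synthetic Lethality")
  )
  ids <- c("A", "B", "C")
  pos <- build_class_matrix(edges, "positive", query_ids = ids, array_ids = ids)
  neg <- build_class_matrix(edges, "negative", query_ids = ids, array_ids = ids)
  for (cm in list(pos, neg)) {
    expect_equal(unclass(cm)["A", "B"], "excluded")
    expect_equal(unclass(cm)["B", "A"], "excluded")
  }
  expect_equal(unclass(pos)["A", "C"], "non_interacting")
})

test_that("an empty edge list labels all non-self pairs non-interacting", {
  cm <- build_class_matrix(edges_tbl(character(0), character(0), character(0)),
    "negative",
    query_ids = c("A", "B"), array_ids = c("C", "D")
  )
  expect_true(all(unclass(cm) == "non_interacting"))
})

test_that("exclusion edges remove both orientations", {
  edges <- edges_tbl("A", "B", "Negative Genetic")
  excl <- edges_tbl("B", "A", "Negative Genetic") # flipped orientation
  cm <- build_class_matrix(edges, "negative",
    query_ids = c("A", "B"), array_ids = c("A", "B"),
    exclude_edges = excl
  )
  expect_equal(unclass(cm)["A", "B"], "excluded")
  expect_equal(unclass(cm)["B", "A"], "excluded")
})

test_that("category matching is case-insensitive and both lethality spellings work", {
  edges <- edges_tbl(
    c("A", "C"), c("B", "D"),
    c("  synthetic lethal ", "SYNTHETIC LETHALITY")
  )
  cm <- build_class_matrix(edges, "negative",
    query_ids = c("A", "C"), array_ids = c("B", "D")
  )
  expect_equal(unclass(cm)["A", "B"], "interacting")
  expect_equal(unclass(cm)["C", "D"], "interacting")
})

test_that("unknown categories warn by default and error in strict mode", {
  edges <- edges_tbl("A", "B", "Dosage Rescue")
  expect_warning(
    build_class_matrix(edges, "positive", query_ids = "A", array_ids = "B"),
    "unmapped"
  )
  expect_error(
    build_class_matrix(edges, "positive",
      query_ids = "A", array_ids = "B", strict = TRUE
    ),
    "unmapped"
  )
})

test_that("label counts always sum to the universe size", {
  set.seed(8)
  genes <- sprintf("G%02d", 1:12)
  edges <- edges_tbl(
    sample(genes, 20, replace = TRUE), sample(genes, 20, replace = TRUE),
    sample(c("Positive Genetic", "Negative Genetic", "Synthetic Lethality"),
      20,
      replace = TRUE
    )
  )
  for (cls in c("positive", "negative")) {
    cm <- build_class_matrix(edges, cls, query_ids = genes, array_ids = genes)
    expect_equal(sum(table(unclass(cm))), length(genes)^2)
  }
})

test_that("construction matches a brute-force set-based oracle on random edge sets", {
  set.seed(17)
  for (rep in 1:10) {
    genes <- sprintf("G%02d", seq_len(sample(6:20, 1)))
    n_edges <- sample(5:40, 1)
    edges <- edges_tbl(
      sample(genes, n_edges, replace = TRUE),
      sample(genes, n_edges, replace = TRUE),
      sample(
        c(
          "Positive Genetic", "Phenotypic Suppression",
          "Negative Genetic", "Synthetic Lethality"
        ),
        n_edges,
        replace = TRUE
      )
    )
    excl <- edges[sample(nrow(edges), 2), ]
    qs <- sample(genes, min(8, length(genes)))
    as <- sample(genes, min(8, length(genes)))
    for (cls in c("positive", "negative")) {
      got <- build_class_matrix(edges, cls,
        query_ids = qs, array_ids = as, exclude_edges = excl
      )
      oracle <- class_matrix_oracle(edges, cls, qs, as, exclude_edges = excl)
      expect_equal(unclass(got), oracle, ignore_attr = TRUE)
    }
  }
})

test_that("restrict_labels preserves request order and drops excluded pairs", {
  edges <- edges_tbl(c("A", "C"), c("B", "B"), c("Positive Genetic", "Positive Genetic"))
  excl <- edges_tbl("C", "B", "Positive Genetic")
  ids <- c("A", "B", "C", "D")
  cm <- build_class_matrix(edges, "positive",
    query_ids = ids, array_ids = ids, exclude_edges = excl
  )
  pairs <- data.frame(
    query = c("D", "A", "C", "B"),
    array = c("A", "B", "B", "D")
  )
  res <- restrict_labels(cm, pairs)
  expect_equal(res$index, c(1L, 2L, 4L)) # (C, B) excluded
  expect_equal(res$labels, c("non_interacting", "interacting", "non_interacting"))
  expect_equal(res$binary, c(0L, 1L, 0L))
  expect_error(
    restrict_labels(cm, data.frame(query = "ZZ", array = "A")),
    "universe"
  )
})

test_that("all pairs excluded yields an empty label vector", {
  edges <- edges_tbl(c("A", "A"), c("B", "B"), c("Positive Genetic", "Negative Genetic"))
  cm <- build_class_matrix(edges, "positive",
    query_ids = c("A", "B"), array_ids = c("A", "B")
  )
  res <- restrict_labels(cm, data.frame(
    query = c("A", "B", "A"), array = c("B", "A", "A")
  ))
  expect_length(res$labels, 0)
  expect_length(res$index, 0)
})
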