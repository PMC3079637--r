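test_that("write/read round-trips identifiers, values and missingness", {
  cases <- list(
    dense = fitness_matrix(matrix(c(1, 0.52, 0.83, 0.4, 0, 1.21), 2, 3),
      query_ids = c("qA", "qB"), array_ids = c("a1", "a2", "a3")
    ),
    with_missing = fitness_matrix(matrix(c(1, NA, 0.5, 0.25), 2, 2),
      query_ids = c("qA", "qB"), array_ids = c("a1", "a2")
    ),
    one_by_one = fitness_matrix(matrix(0.7), "qA", "a1")
  )
  for (fm in cases) {
    path <- tempfile(fileext = ".tsv")
    write_matrix(fm, path)
    back <- read_fitness_matrix(path)
    expect_identical(rownames(back), rownames(fm))
    expect_identical(colnames(back), colnames(fm))
    expect_equal(unclass(back), unclass(fm), ignore_attr = TRUE)
    expect_identical(is.na(back), is.na(fm), ignore_attr = TRUE)
  }
})

test_that("missing token cells become missing on read", {
  path <- write_tsv_lines(c(
    "id\ta1\ta2",
    "q1\t1.0\tNA",
    "q2\t0.5\t0.8"
  ))
  fm <- read_fitness_matrix(path, missing_token = "NA")
  expect_true(is.na(fm["q1", "a2"]))
  expect_equal(sum(is.na(fm)), 1L)
})

test_that("negative fitness values are rejected with location", {
  path <- write_tsv_lines(c(
    "id\ta1\ta2",
    "q1\t1.0\t-0.2"
  ))
  expect_error(read_fitness_matrix(path), "q1.*a2|negative")
})

test_that("ragged rows and malformed headers are format errors", {
  ragged <- write_tsv_lines(c(
    "id\ta1\ta2",
    "q1\t1.0\t0.5",
    "q2\t0.3"
  ))
  expect_error(read_fitness_matrix(ragged), "ragged")
  no_header <- write_tsv_lines(c("id", "q1"))
  expect_error(read_fitness_matrix(no_header), "header|malformed")
})

test_that("score matrices with negative values round-trip when validation is off", {
  sm <- score_matrix(matrix(c(-0.4, 0.2, 0, NA), 2, 2),
    query_ids = c("q1", "q2"), array_ids = c("a1", "a2")
  )
  path <- tempfile(fileext = ".tsv")
  write_matrix(sm, path)
  expect_error(read_fitness_matrix(path), "negative")
  back <- read_fitness_matrix(path, validate_nonnegative = FALSE)
  expect_s3_class(back, "score_matrix")
  expect_equal(unclass(back), unclass(sm), ignore_attr = TRUE)
})

test_that("duplicate strains merge by the mean over present values", {
  fm <- fitness_matrix(rbind(c(1, 2), c(3, 4)),
    query_ids = c("gA", "gA"), array_ids = c("a1", "a2")
  )
  merged <- merge_duplicates(fm)
  expect_equal(nrow(merged), 1L)
  expect_equal(as.vector(unclass(merged)), c(2, 3))

  # missing entries are ignored, not treated as zero
  fm2 <- fitness_matrix(rbind(c(1, NA), c(3, 4)),
    query_ids = c("gA", "gA"), array_ids = c("a1", "a2")
  )
  expect_equal(as.vector(unclass(merge_duplicates(fm2))), c(2, 4))

  # a cell missing in every duplicate stays missing
  fm3 <- fitness_matrix(rbind(c(1, NA), c(3, NA)),
    query_ids = c("gA", "gA"), array_ids = c("a1", "a2")
  )
  expect_true(is.na(unclass(merge_duplicates(fm3))[1, 2]))
})

test_that("merge_duplicates is idempotent and leaves unique strains untouched", {
  set.seed(42)
  W <- matrix(runif(20), 4, 5)
  fm <- fitness_matrix(W,
    query_ids = c("g1", "g2", "g2", "g3"),
    array_ids = c("a1", "a2", "a3", "a3", "a4")
  )
  m1 <- merge_duplicates(fm)
  expect_false(anyDuplicated(rownames(m1)) > 0)
  expect_false(anyDuplicated(colnames(m1)) > 0)
  expect_identical(unclass(merge_duplicates(m1)), unclass(m1))
  # unique strain row g1, unique columns a1/a4 are unchanged
  expect_equal(unclass(m1)["g1", "a1"], W[1, 1])
  expect_equal(unclass(m1)["g3", "a4"], W[4, 5])
})

test_that("merge_duplicates commutes with permutation of duplicate rows", {
  set.seed(7)
  W <- matrix(runif(12), 3, 4)
  ids <- c("gA", "gB", "gA")
  fm <- fitness_matrix(W, query_ids = ids, array_ids = paste0("a", 1:4))
  perm <- c(3, 2, 1) # swap the two gA rows
  fm_perm <- fitness_matrix(W[perm, ],
    query_ids = ids[perm],
    array_ids = paste0("a", 1:4)
  )
  a <- unclass(merge_duplicates(fm))
  b <- unclass(merge_duplicates(fm_perm))
  expect_equal(a[sort(rownames(a)), ], b[sort(rownames(b)), ])
})

test_that("edge lists read with default and custom columns, with organism filter", {
  path <- write_tsv_lines(c(
    paste("Systematic Name Interactor A", "Systematic Name Interactor B",
      "Experimental System", "Organism Interactor A",
      sep = "\t"
    ),
    "YAL001C\tYBR001W\tPositive Genetic\t559292",
    "YAL002C\tYBR002W\tSynthetic Lethality\t559292",
    "HSA1\tHSA2\tNegative Genetic\t9606",
    "YAL003C\tYBR003W\tPhenotypic Suppression\t559292",
    "YAL004C\tYBR004W\tNegative Genetic\t559292"
  ))
  all_edges <- read_edge_list(path)
  expect_equal(nrow(all_edges), 5L)
  expect_named(all_edges, c("gene_a", "gene_b", "category", "source"))
  yeast <- read_edge_list(path, organism_filter = "559292")
  expect_equal(nrow(yeast), 4L)
  expect_false("HSA1" %in% yeast$gene_a)
})

test_that("edge files lacking a named column are format errors", {
  path <- write_tsv_lines(c(
    "A\tB",
    "g1\tg2"
  ))
  expect_error(read_edge_list(path), "column")
})
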