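test_that("intersection matches pairs by query and array identifier", {
  a <- fitness_matrix(matrix(runif(9, 0.1, 1), 3, 3),
    query_ids = c("q1", "q2", "q3"), array_ids = c("a1", "a2", "a3")
  )
  b <- fitness_matrix(matrix(runif(4, 0.1, 1), 2, 2),
    query_ids = c("q2", "q3"), array_ids = c("a1", "a3")
  )
  inter <- intersect_datasets(a, b)
  expect_equal(nrow(inter), 4L)
  expect_setequal(
    paste(inter$query, inter$array),
    c("q2 a1", "q2 a3", "q3 a1", "q3 a3")
  )
  i <- which(inter$query == "q2" & inter$array == "a3")
  expect_equal(inter$value_a[i], unclass(a)["q2", "a3"])
  expect_equal(inter$value_b[i], unclass(b)["q2", "a3"])
})

test_that("disjoint identifier sets give an empty intersection, not an error", {
  a <- fitness_matrix(matrix(1, 2, 2), c("q1", "q2"), c("a1", "a2"))
  b <- fitness_matrix(matrix(1, 2, 2), c("x1", "x2"), c("y1", "y2"))
  expect_message(inter <- intersect_datasets(a, b), "empty")
  expect_equal(nrow(inter), 0L)
})

test_that("transposed matching finds flipped orientations in symmetric screens", {
  a <- fitness_matrix(matrix(0.5, 1, 1), "gA", "gB")
  # b carries the pair only in the flipped orientation
  b <- fitness_matrix(matrix(0.7, 1, 1), "gB", "gA")
  expect_message(plain <- intersect_datasets(a, b), "empty")
  expect_equal(nrow(plain), 0L)
  flipped <- intersect_datasets(a, b, allow_transpose = TRUE)
  expect_equal(nrow(flipped), 1L)
  expect_equal(flipped$value_b, 0.7)

  # both orientations present in b: values averaged
  b2 <- fitness_matrix(
    matrix(c(1, 0.9, 0.3, 1), 2, 2,
      dimnames = list(c("gA", "gB"), c("gA", "gB"))
    )
  )
  both <- intersect_datasets(a, b2, allow_transpose = TRUE)
  expect_equal(both$value_b, (0.3 + 0.9) / 2)
})

test_that("correlations recover exact coefficients on constructed vectors", {
  a <- c(0.3, 1.1, 0.8, 0.2, 0.9)
  affine <- correlations(a, 2 * a + 1)
  expect_equal(affine$pearson, 1)
  expect_equal(affine$spearman, 1)
  mono <- correlations(a, exp(a))
  expect_equal(mono$spearman, 1)
  expect_lt(mono$pearson, 1)
  hand <- correlations(c(1, 2, 3), c(3, 1, 2))
  expect_equal(hand$spearman, -0.5)
})

test_that("degenerate correlation inputs are flagged, not raised", {
  few <- correlations(c(1, 2), c(2, 1))
  expect_false(few$ok)
  expect_true(is.na(few$pearson))
  const <- correlations(c(1, 1, 1), c(1, 2, 3))
  expect_false(const$ok)
})

test_that("a screen predicts its own extreme tail perfectly", {
  set.seed(3)
  s <- score_matrix(matrix(rnorm(400), 20, 20))
  inter <- intersect_datasets(s, s)
  for (tail in c("positive", "negative")) {
    res <- extreme_agreement_auc(s, s, inter, tail_fraction = 0.05, tail = tail)
    expect_true(res$ok)
    expect_equal(res$auc, 1.0)
  }
})

test_that("extreme agreement equals the Mann-Whitney fraction on a hand fixture", {
  ref <- c(10, 9, 1, 2, 3, 4, 5, 6, 7, 8) # top-2 tail = pairs 1, 2
  prd <- c(9, 5, 1, 2, 3, 4, 6, 7, 8, 10)
  s_ref <- score_matrix(matrix(ref, 2, 5))
  s_prd <- score_matrix(matrix(prd, 2, 5))
  inter <- intersect_datasets(s_ref, s_prd)
  res <- extreme_agreement_auc(s_ref, s_prd, inter,
    tail_fraction = 0.2, tail = "positive"
  )
  labels <- as.integer(inter$value_a >= sort(inter$value_a, decreasing = TRUE)[2])
  expect_equal(res$auc, auc_oracle(inter$value_b, labels))
})

test_that("extreme agreement is invariant to monotone transforms of the predictor", {
  set.seed(4)
  ref <- score_matrix(matrix(rnorm(200), 10, 20))
  prd_vals <- matrix(rnorm(200), 10, 20)
  prd <- score_matrix(prd_vals)
  prd_t <- score_matrix(exp(3 * prd_vals) + 2)
  inter1 <- intersect_datasets(ref, prd)
  inter2 <- intersect_datasets(ref, prd_t)
  a1 <- extreme_agreement_auc(ref, prd, inter1, 0.05, "positive")
  a2 <- extreme_agreement_auc(ref, prd_t, inter2, 0.05, "positive")
  expect_equal(a1$auc, a2$auc)
})

test_that("hypergeometric upper tail matches hand enumeration and clamps", {
  expect_equal(hypergeom_upper(10, 4, 3, 2), 1 / 3)
  expect_equal(hypergeom_upper(50, 10, 5, 0), 0.99) # certain event clamped
  expect_equal(hypergeom_upper(10000, 200, 200, 200), 1e-100) # never below floor
  expect_error(hypergeom_upper(10, 12, 3, 1), "require")
  expect_error(hypergeom_upper(10, 4, 3, 4), "require")
})

test_that("enrichment concentrates in a packed corner cell of a 2x2 grid", {
  # ranks 1..16 on both axes; all 4 positives occupy the top-left cell
  a_ranks <- 1:16
  b_ranks <- 1:16
  pos <- as.integer(a_ranks <= 4)
  neg <- integer(16)
  g <- enrichment_grid(a_ranks, b_ranks, pos, neg, grid_dim = 2)
  expect_equal(g$counts, rbind(c(8, 0), c(0, 8)))
  expect_equal(g$positive_p[1, 1], hypergeom_upper(16, 4, 8, 4))
  expect_equal(g$positive_p[2, 2], 0.99)
  expect_equal(g$negative_p[1, 1], 0.99) # no negatives anywhere
})

test_that("grid counts and found totals are conserved on random inputs", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 300
    a <- rank(rnorm(n))
    b <- rank(rnorm(n))
    pos <- rbinom(n, 1, 0.05)
    neg <- rbinom(n, 1, 0.08)
    g <- enrichment_grid(a, b, pos, neg, grid_dim = 6)
    expect_equal(sum(g$counts), n)
    expect_equal(sum(g$positive_found), sum(pos))
    expect_equal(sum(g$negative_found), sum(neg))
    expect_true(all(g$positive_p >= 1e-100 & g$positive_p <= 0.99))
  }
})

test_that("grids need at least as many pairs as cells", {
  expect_error(
    enrichment_grid(1:8, 1:8, integer(8), integer(8), grid_dim = 3),
    "fewer pairs"
  )
  expect_error(
    enrichment_grid(1:10, 1:9, integer(10), integer(10), grid_dim = 2),
    "aligned"
  )
})

test_that("tidy produces one row per cell and class", {
  g <- enrichment_grid(1:16, 16:1, rbinom(16, 1, 0.3), rbinom(16, 1, 0.3),
    grid_dim = 2
  )
  td <- tidy(g)
  expect_equal(nrow(td), 8L)
  expect_setequal(unique(td$class), c("positive", "negative"))
})
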