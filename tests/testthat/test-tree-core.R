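test_that("Newick parsing handles the worked toy trees", {
  tr <- fig_tree()
  expect_equal(tr$n_leaf, 4L)
  expect_equal(tr$labels, c("A", "B", "C", "D"))
  expect_equal(tr$brlen[tr$root], 1)

  single <- read_planted_tree("A:1;")
  expect_equal(single$n_leaf, 1L)
  expect_equal(single$brlen[single$root], 1)
  expect_equal(leaf_depths(single)$depth, 0L)

  expect_error(read_planted_tree(""), "empty")
  expect_error(read_planted_tree("((A,B;"), "malformed")
  expect_error(read_planted_tree(text = "A;", file = "x"), "exactly one")
})

test_that("polytomies resolve to zero-length cascades preserving covariance", {
  tri <- read_planted_tree("((A,B),C,D);")
  expect_equal(tri$n_leaf, 4L)
  # original multifurcating covariance via edge-path sums, done by hand:
  # unit lengths, planted 0; lca(A,B) one edge above root, all others at root
  C_expected <- rbind(c(2, 1, 0, 0), c(1, 2, 0, 0),
                      c(0, 0, 1, 0), c(0, 0, 0, 1))
  dimnames(C_expected) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  expect_equal(covariance_dense(tri), C_expected)
  # cascade edges have zero length
  expect_true(any(tri$brlen == 0))
})

test_that("write -> read round trip preserves topology, lengths, leaf order", {
  for (tr in random_tree_batch(8, n_range = 2:40, seed = 7)) {
    back <- read_planted_tree(write_planted_tree(tr))
    expect_equal(back$labels, tr$labels)
    expect_equal(back$parent, tr$parent)
    expect_equal(back$brlen, tr$brlen, tolerance = 1e-9)
  }
})

test_that("leaf depths and external path length follow both conventions", {
  tr <- fig_tree()
  expect_equal(leaf_depths(tr, planted = TRUE)$depth, rep(3L, 4))
  expect_equal(leaf_depths(tr, planted = FALSE)$depth, rep(2L, 4))
  expect_equal(external_path_length(tr, planted = TRUE), 12)

  cat3 <- caterpillar_tree(3)
  expect_equal(sort(leaf_depths(cat3)$depth), c(1L, 2L, 2L))
  expect_equal(external_path_length(cat3), 5)
  expect_equal(external_path_length(caterpillar_tree(4), planted = TRUE), 13)

  # the two conventions differ by exactly the leaf count
  for (tr in random_tree_batch(6, seed = 3)) {
    expect_equal(
      external_path_length(tr, planted = TRUE) -
        external_path_length(tr, planted = FALSE),
      tr$n_leaf
    )
  }
})

test_that("subtree leaf counts match the worked examples", {
  counts <- subtree_leaf_counts(fig_tree())
  expect_equal(counts$n_leaves[!counts$is_leaf], c(2L, 2L, 4L))
  expect_true(all(counts$n_leaves[counts$is_leaf] == 1L))
  chain <- subtree_leaf_counts(caterpillar_tree(4))
  expect_equal(sort(chain$n_leaves[!chain$is_leaf]), c(2L, 3L, 4L))
})

test_that("minor split medians match enumeration", {
  ms <- minor_split_summary(caterpillar_tree(4))
  expect_equal(ms$clade_size, c(4L, 3L, 2L))
  expect_equal(ms$median_minor, c(1, 1, 1))

  ms <- minor_split_summary(fig_tree())
  expect_equal(ms$clade_size, c(4L, 2L))
  expect_equal(ms$median_minor, c(2, 1))

  # complete balanced 8-leaf tree
  bal8 <- read_planted_tree(
    "(((a,b),(c,d)),((e,f),(g,h)));")
  ms <- minor_split_summary(bal8)
  expect_equal(ms$median_minor[ms$clade_size == 8], 4)
  expect_equal(ms$median_minor[ms$clade_size == 4], 2)
  expect_equal(ms$median_minor[ms$clade_size == 2], 1)

  expect_equal(nrow(minor_split_summary(read_planted_tree("A:1;"))), 0L)
})

test_that("split clade sizes sum to the unplanted external path length", {
  for (tr in random_tree_batch(10, n_range = 2:64, seed = 12)) {
    internal <- which(!tr$is_leaf)
    both_children <- tr$n_desc[tr$kids[internal, 1L]] +
      tr$n_desc[tr$kids[internal, 2L]]
    expect_equal(sum(both_children), external_path_length(tr))
  }
})

test_that("ape round trip agrees", {
  tr <- sample_tree(20, "critical", seed = 5, edge_lengths = "exponential",
                    planted_length = 0.5)
  ph <- as_phylo(tr)
  back <- as_planted_tree(ph)
  expect_equal(back$brlen, tr$brlen, tolerance = 1e-12)
  expect_equal(back$labels, tr$labels)
})
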