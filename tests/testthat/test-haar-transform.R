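test_that("basis wavelets match the worked examples", {
  phi <- as.matrix(haar_basis(fig_tree()))
  expect_equal(unname(phi[, "0"]), rep(0.5, 4))
  expect_equal(unname(phi[, "7"]), c(0.5, 0.5, -0.5, -0.5))   # top split
  expect_equal(unname(phi[, "3"]), c(1, -1, 0, 0) / sqrt(2))
  expect_equal(unname(phi[, "6"]), c(0, 0, 1, -1) / sqrt(2))

  phi3 <- as.matrix(haar_basis(caterpillar_tree(3)))
  expect_equal(unname(phi3[, "5"]),
               c(sqrt(2 / 3), -1 / sqrt(6), -1 / sqrt(6)))
})

test_that("wavelets are orthonormal, zero-sum off the root", {
  for (tr in c(random_tree_batch(6, n_range = 2:64, seed = 21),
               list(sample_tree(256, "critical", seed = 8)))) {
    phi <- as.matrix(haar_basis(tr))
    expect_lt(max(abs(crossprod(phi) - diag(tr$n_leaf))), 1e-12)
    colsum <- colSums(phi)
    expect_lt(max(abs(colsum[-1])), 1e-12)       # only phi_o meets constants
    expect_equal(unname(colsum[1]), sqrt(tr$n_leaf))
  }
})

test_that("dense covariance matches the hand-computed example and Eq-style PSD", {
  C <- covariance_dense(fig_tree())
  expect_equal(unname(C), rbind(c(3, 2, 1, 1), c(2, 3, 1, 1),
                                c(1, 1, 3, 2), c(1, 1, 2, 3)))
  single <- read_planted_tree("A:2.5;")
  expect_equal(unname(covariance_dense(single)), matrix(2.5))
  expect_error(covariance_dense(fig_tree(), max_leaves = 2), "sparse")
  for (tr in random_tree_batch(5, seed = 77)) {
    ev <- eigen(covariance_dense(tr), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-9)
  }
})

test_that("sparse transform equals the dense oracle on the toy trees", {
  x <- haar_transform(fig_tree())
  expect_equal(x$lambda$lambda[match(c(0, 7, 3, 6), x$lambda$node)],
               c(7, 3, 1, 1))
  expect_true(all(abs(x$offdiag$value) < 1e-14))

  x3 <- haar_transform(caterpillar_tree(3))
  expect_equal(x3$lambda$lambda[match(c(0, 5, 4), x3$lambda$node)],
               c(16 / 3, 5 / 3, 1))
  nz <- x3$offdiag[abs(x3$offdiag$value) > 1e-12, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(nz$value, -2 * sqrt(2) / 3)
  expect_equal(c(nz$u, nz$v), c(0L, 5L))
})

test_that("sparse transform equals dense Phi' C Phi on random trees", {
  for (tr in random_tree_batch(24, n_range = 2:64, seed = 1001)) {
    x <- haar_transform(tr)
    expect_lt(max(abs(as.matrix(x) - dense_transform(tr))), 1e-10)
  }
})

test_that("transform conserves the trace and keeps lambda nonnegative", {
  for (tr in random_tree_batch(10, seed = 55)) {
    x <- haar_transform(tr)
    expect_equal(sum(x$lambda$lambda),
                 sum(diag(covariance_dense(tr))), tolerance = 1e-10)
    expect_true(all(x$lambda$lambda >= 0))
  }
})

test_that("planted-edge length moves only the root diagonal entry", {
  base <- sample_tree(12, "critical", seed = 4)
  shifted <- base
  shifted$brlen[shifted$root] <- shifted$brlen[shifted$root] + 2.5
  x0 <- haar_transform(base)
  x1 <- haar_transform(shifted)
  expect_equal(x1$lambda$lambda[1] - x0$lambda$lambda[1], 2.5 * 12)
  expect_equal(x1$lambda$lambda[-1], x0$lambda$lambda[-1])
  expect_equal(x1$offdiag$value, x0$offdiag$value)
})

test_that("sparsity statistics and the guaranteed bound behave as derived", {
  x <- haar_transform(fig_tree())
  expect_equal(sparsity_stats(x, "structural")$xi_offdiag, 2 / 12)
  expect_equal(sparsity_stats(x, "numerical")$xi_offdiag, 1)
  expect_equal(sparsity_bound(fig_tree()), 0.875)
  expect_gte(sparsity_bound(fig_tree()),
             1 - sparsity_stats(x, "structural")$xi_offdiag)

  x3 <- haar_transform(caterpillar_tree(3))
  expect_equal(sparsity_stats(x3, "numerical")$xi_offdiag, 4 / 6)
  expect_equal(sparsity_bound(caterpillar_tree(4)), 1)
  expect_error(sparsity_stats(x3, tol = -1), "nonnegative")

  # the bound holds structurally on every sampled tree
  for (tr in random_tree_batch(12, seed = 91)) {
    xr <- haar_transform(tr)
    expect_lte(1 - sparsity_stats(xr, "structural")$xi_offdiag,
               sparsity_bound(tr) + 1e-12)
  }
})

test_that("structural sparsity of critical trees increases with size", {
  set.seed(17)
  mean_xi <- vapply(2^c(6, 8, 10, 12), function(n) {
    mean(vapply(1:10, function(r) {
      sparsity_stats(haar_transform(sample_tree(n, "critical")),
                     "structural")$xi_offdiag
    }, 0))
  }, 0)
  expect_true(all(diff(mean_xi) > 0))
})

test_that("Matrix Market output round-trips", {
  tr <- sample_tree(15, "critical", seed = 6, edge_lengths = "exponential")
  x <- haar_transform(tr)
  mtx <- withr::local_tempfile(fileext = ".mtx")
  dg <- withr::local_tempfile(fileext = ".tsv")
  write_transform(x, mtx, dg)
  M <- as.matrix(Matrix::readMM(mtx))
  expect_equal(unname(M), unname(as.matrix(x)), tolerance = 1e-12)
  diag_tbl <- readr::read_tsv(dg, show_col_types = FALSE)
  expect_equal(diag_tbl$lambda, x$lambda$lambda)
})
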