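test_that("DKW resample counts follow the inequality", {
  expect_equal(dkw_sample_size(1e-4, 0.01), 264915869)
  # delta = 2/e^2 makes log(2/delta) = 2 exactly
  expect_equal(dkw_sample_size(0.5, 2 / exp(2)), 4)
  # halving epsilon quadruples N (up to ceiling)
  n1 <- dkw_sample_size(0.01, 0.05)
  n2 <- dkw_sample_size(0.005, 0.05)
  expect_lte(abs(n2 - 4 * n1), 4)
  expect_error(dkw_sample_size(0, 0.1), "positive")
  expect_error(dkw_sample_size(0.1, 1.5), "in \\(0, 1\\)")
})

test_that("multivariate hypergeometric draws are exact", {
  set.seed(5)
  # exhaustive draw returns the pool
  full <- rmultihyper(20, c(3, 2), 5)
  expect_true(all(full[1, ] == 3 & full[2, ] == 2))
  # zero-pool categories always zero, pool conserved with the complement
  x <- rmultihyper(200, c(4, 0, 7, 2), 6)
  expect_true(all(x[2, ] == 0))
  expect_true(all(colSums(x) == 6))
  expect_true(all(x <= c(4, 0, 7, 2)))
  expect_error(rmultihyper(1, c(2, 2), 5), "between 0")

  # P(first coordinate = 0 | pool (2,2), draw 2) = C(2,0)C(2,2)/C(4,2) = 1/6
  y <- rmultihyper(1e5, c(2, 2), 2)
  counts <- tabulate(y[1, ] + 1L, nbins = 3)
  gof <- suppressWarnings(chisq.test(counts, p = c(1, 4, 1) / 6))
  expect_gt(gof$p.value, 1e-3)

  # marginal means: E(x_i) = k pool_i / sum(pool)
  pool <- c(10, 30, 5, 55)
  z <- rmultihyper(2e4, pool, 40)
  expect_equal(rowMeans(z), 40 * pool / 100, tolerance = 0.02)
})

test_that("permutation test is reproducible and handles degenerate inputs", {
  tr <- sample_tree(12, "critical", seed = 3)
  sp <- synthetic_pair(tr, 500, 700, seed = 10)
  p1 <- haar_perm_test(tr, sp$a, sp$b, N = 400, seed = 77)
  p2 <- haar_perm_test(tr, sp$a, sp$b, N = 400, seed = 77)
  expect_identical(p1$results, p2$results)
  # batching must not change the stream-accumulated counts' totals
  expect_true(all(p1$results$exceedances <= 400))

  # identical samples: observed statistics 0, add-one p-values 1 wherever a
  # resampled statistic can be positive
  p3 <- haar_perm_test(tr, sp$a, sp$a, N = 200, seed = 1)
  expect_true(all(p3$results$observed == 0))
  expect_true(all(p3$results$p_raw[p3$results$exceedances == 200] == 1))

  # all pooled mass on one leaf: resampling is deterministic, statistics 0
  a1 <- setNames(c(9, rep(0, 11)), tr$labels)
  p4 <- haar_perm_test(tr, a1, a1 + 0, N = 50, seed = 2)
  expect_true(all(p4$results$observed == 0))
  expect_true(all(p4$results$p_raw == 1))
  p5 <- haar_perm_test(tr, a1, a1 + 0, N = 50, seed = 2,
                       comparison = "strict")
  expect_true(all(p5$results$p_raw == 1 / 50))
  expect_true(all(p5$results$floor_flag))
})

test_that("strict mode floors zero-exceedance p-values at 1/N", {
  tr <- sample_tree(8, "critical", seed = 21)
  comp <- synthetic_composition(tr, seed = 5)
  rb <- (tr$hi[tr$kids[tr$root, 1]] + 1):tr$hi[tr$root]
  sp <- synthetic_pair(tr, 5000, 5000, composition = comp,
                       effect_node = tr$root,
                       effect_size = 0.9 * sum(comp[rb]), seed = 6)
  pt <- haar_perm_test(tr, sp$a, sp$b, N = 100, seed = 9,
                       comparison = "strict", correction = "bonferroni",
                       m = 12)
  top <- pt$results[1, ]
  expect_true(top$floor_flag)
  expect_equal(top$p_raw, 1 / 100)
  expect_equal(top$p_adjusted, 12 / 100)   # reported bound m/N
})

test_that("node subsetting restricts the table", {
  tr <- sample_tree(10, "critical", seed = 13)
  sp <- synthetic_pair(tr, 300, 300, seed = 14)
  nodes <- haar_transform(tr)$lambda$node[-1][1:3]
  pt <- haar_perm_test(tr, sp$a, sp$b, N = 100, seed = 1, nodes = nodes)
  expect_setequal(pt$results$node, nodes)
  expect_error(haar_perm_test(tr, sp$a, sp$b, N = 10, nodes = 999L),
               "unknown node")
})

test_that("p-value adjustments match the standard procedures", {
  expect_equal(adjust_pvalues(0.001, "bonferroni", m = 12), 0.012)
  expect_equal(adjust_pvalues(c(0.2, 0.6), "bonferroni", m = 1), c(0.2, 0.6))
  expect_equal(adjust_pvalues(c(0.001, 0.03), "bonferroni", m = 5),
               p.adjust(c(0.001, 0.03), "bonferroni", n = 5))
  # BH step-up: all three below their thresholds k alpha / m
  bh <- adjust_pvalues(c(0.01, 0.02, 0.04), "benjamini_hochberg")
  expect_true(all(bh <= 0.05))
  expect_equal(bh, p.adjust(c(0.01, 0.02, 0.04), "BH"))
  expect_equal(adjust_pvalues(c(0.3, 0.01), "none"), c(0.3, 0.01))
  expect_equal(adjust_pvalues(0.04, "benjamini_hochberg"), 0.04)
  expect_error(adjust_pvalues(1.2, "bonferroni"), "0, 1")
})

test_that("tidy/glance/autoplot summarize the test object", {
  tr <- sample_tree(10, "critical", seed = 2)
  sp <- synthetic_pair(tr, 400, 400, seed = 3)
  pt <- haar_perm_test(tr, sp$a, sp$b, N = 99, seed = 4)
  expect_identical(tidy(pt), pt$results)
  g <- glance(pt)
  expect_equal(g$N, 99)
  expect_equal(g$n_components, 9L)
  expect_s3_class(autoplot(pt), "ggplot")
})
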