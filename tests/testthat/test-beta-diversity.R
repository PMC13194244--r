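test_that("abundance coercion is strict by default and aligns to leaves", {
  tr <- fig_tree()
  a <- as_abundance(c(C = 2, A = 4), tr)
  expect_equal(unname(a), c(4, 0, 2, 0))
  expect_error(as_abundance(c(A = 1, X = 2), tr), "not found")
  expect_message(ok <- as_abundance(c(A = 1, X = 2), tr, drop_unknown = TRUE),
                 "dropping")
  expect_equal(unname(ok), c(1, 0, 0, 0))
  expect_error(as_abundance(c(A = -1), tr), "nonnegative")
  tb <- tibble::tibble(otu = c("B", "D"), count = c(3, 1))
  expect_equal(unname(as_abundance(tb, tr)), c(0, 3, 0, 1))
})

test_that("Haar coordinates match hand dot products and are linear", {
  tr <- fig_tree()
  basis <- haar_basis(tr)
  f <- c(1, 0, -0.5, -0.5)
  co <- haar_coordinates(basis, f)
  expect_equal(co$delta[match(c(7, 3, 6), co$node)], c(1, 1 / sqrt(2), 0))
  expect_equal(co$delta[co$node == 0], 0)        # compositional difference

  g <- c(0.2, -0.1, 0.4, 0)
  lin <- haar_coordinates(basis, f + g)
  expect_equal(lin$delta,
               co$delta + haar_coordinates(basis, g)$delta)

  # cumsum pass equals dense multiplication
  phi <- as.matrix(basis)
  expect_equal(co$delta, unname(drop(t(phi) %*% f)), tolerance = 1e-14)
})

test_that("Parseval holds on random trees and random signals", {
  set.seed(9)
  for (n in c(2, 17, 64, 256)) {
    tr <- sample_tree(n, "critical")
    basis <- haar_basis(tr)
    f <- rnorm(n)
    co <- haar_coordinates(basis, f)
    expect_equal(sum(co$delta^2), sum(f^2), tolerance = 1e-12)
  }
})

test_that("Haar-like distance reproduces the toy decomposition", {
  tr <- fig_tree()
  d <- haar_distance(tr, c(A = 4), c(C = 2, D = 2))
  expect_equal(d$distance, sqrt(3.5))
  comp <- d$components
  expect_equal(comp$component[match(c(7, 3, 6), comp$node)], c(3, 0.5, 0))
  expect_equal(comp$component[comp$node == 0], 0)
  # with this tree the transform is exactly diagonal: d^2 = f' C f
  f <- d$f
  expect_equal(d$distance^2,
               drop(f %*% covariance_dense(tr) %*% f))
  # metric basics
  expect_equal(haar_distance(tr, c(A = 4), c(A = 4))$distance, 0)
  d_ba <- haar_distance(tr, c(C = 2, D = 2), c(A = 4))
  expect_equal(d_ba$distance, d$distance)
  expect_error(haar_distance(tr, c(A = 0), c(B = 1)), "positive totals")
})

test_that("tidiers and autoplot expose the decomposition", {
  d <- haar_distance(fig_tree(), c(A = 4), c(C = 2, D = 2))
  expect_identical(tidy(d), d$components)
  g <- glance(d)
  expect_equal(g$distance, sqrt(3.5))
  expect_equal(g$n_nonzero, 2L)
  expect_s3_class(autoplot(d), "ggplot")
})

test_that("filtered reconstruction inverts kept coordinates", {
  tr <- fig_tree()
  basis <- haar_basis(tr)
  f <- c(1, 0, -0.5, -0.5)
  co <- haar_coordinates(basis, f)

  all_nodes <- co$node[abs(co$delta) > 0]
  expect_equal(filtered_reconstruction(basis, co, all_nodes)$value, f)
  expect_equal(filtered_reconstruction(basis, co, integer(0))$value,
               rep(0, 4))
  expect_equal(filtered_reconstruction(basis, co, 7L)$value,
               c(0.5, 0.5, -0.5, -0.5))
  expect_error(filtered_reconstruction(basis, co, 99L), "unknown")
})

test_that("grouped differences sum per class and reflect split contrasts", {
  f <- c(t1 = 1, t2 = 0, t3 = -0.5, t4 = -0.5)
  gd <- grouped_difference(f, c(t1 = "left", t2 = "left",
                                t3 = "right", t4 = "right"))
  expect_equal(gd$total[match(c("left", "right"), gd$group)], c(1, -1))
  one <- grouped_difference(f, setNames(rep("all", 4), names(f)))
  expect_equal(one$total, 0)

  # block-mean difference is proportional to the Haar coordinate
  set.seed(44)
  tr <- sample_tree(20, "critical")
  basis <- haar_basis(tr)
  g <- rnorm(20); g <- g - mean(g)
  co <- haar_coordinates(basis, g)
  for (k in c(2, 5, 11)) {
    s <- basis$splits[k, ]
    lmean <- mean(g[s$lo:s$mid]); rmean <- mean(g[(s$mid + 1):s$hi])
    # Delta_v = sqrt(n- n+ / n) (mean_L - mean_R): group-mean contrasts and
    # Haar coordinates carry the same information
    expect_equal(co$delta[co$node == s$node],
                 sqrt(s$n_minus * s$n_plus / (s$n_minus + s$n_plus)) *
                   (lmean - rmean))
  }
})

test_that("OTU tables read and slice by sample", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu_id\ts1\ts2", "A\t4\t0", "C\t0\t2", "D\t0\t2"), tf)
  tb <- read_otu_table(tf)
  expect_equal(names(tb), c("otu_id", "s1", "s2"))
  a <- otu_sample(tb, "s1")
  expect_equal(unname(a), c(4, 0, 0))
  expect_error(otu_sample(tb, "s9"), "no sample column")
  d <- haar_distance(fig_tree(), a, otu_sample(tb, "s2"))
  expect_equal(d$distance, sqrt(3.5))
})
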