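# Shared fixtures, all built in code.

# balanced 4-leaf tree with unit edges everywhere, including the planted edge
fig_tree <- function() read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")

# caterpillar with n leaves, unit edges, unit planted edge: (t1,(t2,(t3,...)))
caterpillar_newick <- function(n) {
  s <- paste0("t", n, ":1")
  for (k in (n - 1):1) s <- paste0("(t", k, ":1,", s, "):1")
  paste0(s, ";")
}
caterpillar_tree <- function(n) read_planted_tree(caterpillar_newick(n))

# dense-oracle transform: materialized Phi^T C Phi
dense_transform <- function(t) {
  phi <- as.matrix(haar_basis(t))
  C <- covariance_dense(t)
  t(phi) %*% C %*% phi
}

# mixed bag of seeded random trees covering both ensembles and length rules
random_tree_batch <- function(n_trees, n_range = 2:64, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_trees), function(k) {
    sample_tree(
      n = sample(n_range, 1),
      law = if (k %% 2 == 0) "critical" else "uniform",
      edge_lengths = if (k %% 4 < 2) "unit" else "exponential",
      planted_length = if (k %% 3 == 0) 0 else runif(1)
    )
  })
}
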