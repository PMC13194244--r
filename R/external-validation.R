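#' Large-scale reference-tree validation
#'
#' Recomputes, for a user-supplied large reference phylogeny (e.g. the 97%
#' Greengenes tree) and optionally a paired OTU table, the headline
#' sparsification and distance quantities: the guaranteed sparsity bound,
#' the structural and numerical sparsity of the Haar-like transform, the
#' median and maximum leaf depth, and — when an OTU table with two sample
#' columns is given — the number of nonzero Haar-components and the largest
#' component with its node. These inputs are large external downloads and
#' are not shipped with the package; the function validates the paths first
#' and fails with an informative error when they are absent.
#'
#' @param tree_file path to the reference tree in Newick format.
#' @param otu_file optional path to a TSV OTU table (see
#'   [read_otu_table()]).
#' @param sample_a,sample_b sample column names of the two environments.
#' @param dense_cap forwarded safety cap: the computation never materializes
#'   the dense covariance, this only guards accidental misuse downstream.
#' @return A one-row tibble with columns `n_leaves`, `bound_vanishing_pct`,
#'   `structural_vanishing_pct`, `numerical_vanishing_pct`,
#'   `median_leaf_depth`, `max_leaf_depth`, and when an OTU table is given
#'   `n_nonzero_components`, `top_component`, `top_node`.
#' @export
external_validation <- function(tree_file, otu_file = NULL,
                                sample_a = NULL, sample_b = NULL,
                                dense_cap = 2048) {
  if (!file.exists(tree_file))
    stop("reference tree not found: ", tree_file,
         " (this validation needs the externally downloaded tree)")
  t <- read_planted_tree(file = tree_file)
  tr <- haar_transform(t)
  st_s <- sparsity_stats(tr, "structural")
  st_n <- sparsity_stats(tr, "numerical")
  dpt <- leaf_depths(t, planted = FALSE)$depth
  out <- tibble(
    n_leaves = t$n_leaf,
    bound_vanishing_pct = 100 * (1 - sparsity_bound(t)),
    structural_vanishing_pct = 100 * st_s$xi_offdiag,
    numerical_vanishing_pct = 100 * st_n$xi_offdiag,
    median_leaf_depth = median(dpt),
    max_leaf_depth = max(dpt)
  )
  if (!is.null(otu_file)) {
    if (!file.exists(otu_file))
      stop("OTU table not found: ", otu_file)
    tb <- read_otu_table(otu_file)
    d <- haar_distance(t, otu_sample(tb, sample_a), otu_sample(tb, sample_b),
                       transform = tr, drop_unknown = TRUE)
    nz <- d$components[d$components$component > 0, ]
    out$n_nonzero_components <- nrow(nz)
    out$top_component <- nz$component[1]
    out$top_node <- nz$node[1]
  }
  out
}
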