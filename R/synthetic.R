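#' Random leaf composition
#'
#' Symmetric Dirichlet(`concentration`) composition over the leaves of a
#' tree, the default environment model of the synthetic generator.
#'
#' @param t a `planted_tree`.
#' @param concentration Dirichlet concentration (default 1, uniform on the
#'   simplex).
#' @param seed optional integer seed.
#' @return Numeric probability vector named by leaf label.
#' @export
synthetic_composition <- function(t, concentration = 1, seed = NULL) {
  stopifnot(inherits(t, "planted_tree"))
  if (!is.null(seed)) set.seed(seed)
  g <- rgamma(t$n_leaf, shape = concentration)
  setNames(g / sum(g), t$labels)
}

#' Shift composition mass across a split
#'
#' Moves probability mass `epsilon` from the right block `L(v+)` of split
#' `v` to the left block `L(v-)`, proportionally within each block, leaving
#' a valid composition. This is the alternative hypothesis of the paired
#' generator: exactly the split `v` (and the path above it) separates the
#' two environments in expectation.
#'
#' @param t a `planted_tree`.
#' @param composition probability vector in leaf order (or named).
#' @param node interior node id of the split to perturb.
#' @param epsilon mass to move; must not exceed the right-block mass.
#' @return The shifted composition.
#' @export
shift_composition <- function(t, composition, node, epsilon) {
  stopifnot(inherits(t, "planted_tree"))
  if (t$is_leaf[node] || node > 2L * t$n_leaf - 1L)
    stop("`node` must be an interior node id")
  p <- as_abundance(composition, t)
  lb <- t$lo[node]:t$hi[t$kids[node, 1L]]
  rb <- (t$hi[t$kids[node, 1L]] + 1L):t$hi[node]
  mr <- sum(p[rb]); ml <- sum(p[lb])
  if (epsilon < 0 || epsilon > mr)
    stop("`epsilon` must lie in [0, right-block mass = ", format(mr), "]")
  if (epsilon > 0) {
    p[rb] <- p[rb] * (1 - epsilon / mr)
    p[lb] <- if (ml > 0) p[lb] * (1 + epsilon / ml) else
      epsilon / length(lb)
  }
  p
}

#' Synthetic paired abundance samples
#'
#' Emulates paired OTU samples from two environments: under the null both
#' samples are independent multinomial draws from one composition (reads as
#' i.i.d. draws from a single layer distribution); under the alternative,
#' environment `a`'s composition is shifted by `effect_size` across the
#' split `effect_node` before sampling. Multinomial sampling is the *data*
#' model here; the pooled multivariate hypergeometric draw is the test's
#' resampling device, not the generator.
#'
#' @param t a `planted_tree`.
#' @param depth_a,depth_b total read counts of the two samples.
#' @param composition leaf probability vector; default symmetric
#'   Dirichlet(1) via [synthetic_composition()].
#' @param effect_node interior node id to perturb (`NULL` = null model).
#' @param effect_size mass shifted across the split in environment `a`.
#' @param seed optional integer seed; the same seed reproduces the same
#'   pair exactly.
#' @return A list with `a`, `b` (named integer count vectors),
#'   `composition`, `composition_a` (the shifted one) and `truth` — a
#'   one-row tibble (`effect_node`, `effect_size`; `NA` node under the
#'   null).
#' @export
synthetic_pair <- function(t, depth_a = 10000, depth_b = 10000,
                           composition = NULL, effect_node = NULL,
                           effect_size = 0, seed = NULL) {
  stopifnot(inherits(t, "planted_tree"))
  if (depth_a < 1 || depth_b < 1) stop("sampling depths must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(composition)) composition <- synthetic_composition(t)
  p_b <- as_abundance(composition, t)
  p_b <- p_b / sum(p_b)
  p_a <- if (!is.null(effect_node) && effect_size > 0)
    shift_composition(t, p_b, effect_node, effect_size) else p_b
  a <- setNames(as.integer(rmultinom(1, depth_a, p_a)), t$labels)
  b <- setNames(as.integer(rmultinom(1, depth_b, p_b)), t$labels)
  list(a = a, b = b, composition = p_b, composition_a = p_a,
       truth = tibble(effect_node = effect_node %||% NA_integer_,
                      effect_size = effect_size))
}
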