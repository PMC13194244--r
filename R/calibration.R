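#' Null calibration of the component permutation test
#'
#' Repeatedly draws paired samples from one composition (the null of
#' compositionally identical environments), runs the permutation test, and
#' records per-component rejection rates at level `alpha` on the raw
#' p-values. Under a well-calibrated test each rate should sit near the
#' discrete null rejection probability implied by `N` resamples.
#'
#' @param t a `planted_tree`.
#' @param reps number of replicate pairs.
#' @param N resamples per test.
#' @param depth_a,depth_b sample totals.
#' @param alpha significance level applied to the raw p-values.
#' @param composition leaf probability vector; default symmetric
#'   Dirichlet(1), drawn once and shared by every replicate.
#' @param comparison p-value convention, see [haar_perm_test()].
#' @param seed optional integer seed.
#' @return A list with `rates` — tibble (`node`, `rejections`, `reps`,
#'   `rate`) — and `pvals`, the components-by-replicates matrix of raw
#'   p-values for further diagnostics.
#' @export
null_calibration <- function(t, reps = 500, N = 2000, depth_a = 10000,
                             depth_b = 10000, alpha = 0.05,
                             composition = NULL,
                             comparison = "add_one", seed = NULL) {
  stopifnot(inherits(t, "planted_tree"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(composition)) composition <- synthetic_composition(t)
  n_comp <- t$n_leaf - 1L
  pv <- matrix(NA_real_, n_comp, reps)
  nodes <- NULL
  for (r in seq_len(reps)) {
    sp <- synthetic_pair(t, depth_a, depth_b, composition = composition)
    pt <- haar_perm_test(t, sp$a, sp$b, N = N, correction = "none",
                         comparison = comparison)
    res <- pt$results[order(pt$results$node), ]
    if (is.null(nodes)) nodes <- res$node
    pv[, r] <- res$p_raw
  }
  rej <- rowSums(pv <= alpha)
  list(
    rates = tibble(node = nodes, rejections = rej, reps = reps,
                   rate = rej / reps),
    pvals = pv
  )
}

#' Power of the permutation test against split-shift alternatives
#'
#' For each effect size, draws replicate pairs in which environment `a`'s
#' composition is shifted by that much mass across `effect_node`, and
#' records how often the raw p-value at that node falls at or below
#' `alpha`.
#'
#' @inheritParams null_calibration
#' @param effect_node interior node id carrying the true effect.
#' @param effect_sizes numeric grid of mass shifts (0 = null).
#' @return A tibble (`effect_size`, `rejections`, `reps`, `rate`).
#' @export
power_curve <- function(t, effect_node, effect_sizes = c(0, 0.05, 0.1, 0.2),
                        reps = 200, N = 500, depth_a = 10000,
                        depth_b = 10000, alpha = 0.05, composition = NULL,
                        seed = NULL) {
  stopifnot(inherits(t, "planted_tree"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(composition)) composition <- synthetic_composition(t)
  rates <- vapply(effect_sizes, function(eps) {
    hits <- 0L
    for (r in seq_len(reps)) {
      sp <- synthetic_pair(t, depth_a, depth_b, composition = composition,
                           effect_node = effect_node, effect_size = eps)
      pt <- haar_perm_test(t, sp$a, sp$b, N = N, correction = "none")
      hits <- hits + as.integer(
        pt$results$p_raw[pt$results$node == effect_node] <= alpha)
    }
    hits
  }, 0L)
  tibble(effect_size = effect_sizes, rejections = rates, reps = reps,
         rate = rates / reps)
}
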