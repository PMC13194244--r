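#' Split laws of Markov branching random binary trees
#'
#' Probability that a clade of `n` leaves splits into ordered subclades of
#' sizes `(i, n - i)`:
#' * `"critical"` — the critical beta-splitting law
#'   `q(n, i) = n / (2 h_{n-1} i (n - i))`, with `h_m` the m-th harmonic
#'   number. Trees from this law have the `sqrt(n)` median minor split size
#'   observed in real phylogenies.
#' * `"uniform"` — the split law of the uniform distribution over ordered
#'   binary tree shapes, `q(n, i) = Cat(i-1) Cat(n-i-1) / Cat(n-1)` with
#'   Catalan numbers `Cat`.
#'
#' Both laws are symmetric, `q(n, i) = q(n, n - i)`, and strictly positive.
#'
#' @param n clade size, at least 2.
#' @param law `"critical"` or `"uniform"`.
#' @return Numeric probability vector over `i = 1..n-1`.
#' @examples
#' split_pmf(4, "critical")  # 4/11, 3/11, 4/11
#' split_pmf(4, "uniform")   # 2/5, 1/5, 2/5
#' @export
split_pmf <- function(n, law = c("critical", "uniform")) {
  law <- match.arg(law)
  if (n < 2) stop("`n` must be at least 2")
  i <- seq_len(n - 1)
  if (law == "critical") {
    h <- sum(1 / seq_len(n - 1))
    n / (2 * h * i * (n - i))
  } else {
    # log Catalan: Cat(k) = choose(2k, k) / (k + 1)
    lcat <- function(k) lchoose(2 * k, k) - log(k + 1)
    exp(lcat(i - 1) + lcat(n - i - 1) - lcat(n - 1))
  }
}

#' Draw clade split sizes
#'
#' Samples from [split_pmf()]. For the critical law the draw is exact and
#' O(log n): since `n / (i (n - i)) = 1/i + 1/(n - i)`, the law is a balanced
#' mixture of `J` and `n - J` where `P(J = j)` is proportional to `1/j`; `J`
#' is drawn by inverse-CDF bisection on the harmonic numbers.
#'
#' @inheritParams split_pmf
#' @param size number of draws.
#' @return Integer vector of left-clade sizes in `1..n-1`.
#' @export
sample_split <- function(n, law = c("critical", "uniform"), size = 1) {
  law <- match.arg(law)
  if (n < 2) stop("`n` must be at least 2")
  if (n == 2) return(rep(1L, size))
  if (law == "critical") {
    cumh <- cumsum(1 / seq_len(n - 1))
    u <- runif(size) * cumh[n - 1]
    j <- findInterval(u, cumh, left.open = TRUE) + 1L
    flip <- runif(size) < 0.5
    ifelse(flip, j, n - j)
  } else {
    q <- split_pmf(n, "uniform")
    sample.int(n - 1L, size, replace = TRUE, prob = q)
  }
}

#' Simulate a random binary tree
#'
#' Generates a planted binary tree by recursive random binary partitioning:
#' a clade of size `m >= 2` splits into ordered subclades of sizes
#' `(i, m - i)` drawn from the chosen split law, recursing until singleton
#' clades. Leaves are labelled `t1..tn` in left-to-right order.
#'
#' @param n number of leaves, at least 1.
#' @param law `"critical"` (critical beta-splitting) or `"uniform"` (uniform
#'   over ordered binary shapes).
#' @param edge_lengths `"unit"` for unit lengths or `"exponential"` for
#'   independent Exponential(`rate`) lengths.
#' @param rate rate of the exponential edge-length distribution.
#' @param planted_length length of the planted edge. Default 0 (it only
#'   shifts the root diagonal entry of the Haar-like transform).
#' @param seed optional integer seed for reproducibility.
#' @return A `planted_tree`.
#' @examples
#' tr <- sample_tree(10, "critical", seed = 1)
#' external_path_length(tr)
#' @export
sample_tree <- function(n, law = c("critical", "uniform"),
                        edge_lengths = c("unit", "exponential"), rate = 1,
                        planted_length = 0, seed = NULL) {
  law <- match.arg(law)
  edge_lengths <- match.arg(edge_lengths)
  if (n < 1) stop("`n` must be at least 1")
  if (rate <= 0) stop("`rate` must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_nodes <- 2L * n - 1L
  kids <- vector("list", n_nodes)
  size <- integer(n_nodes)
  size[1L] <- n
  next_free <- 2L
  stack <- 1L                       # raw ids of clades awaiting a split
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    m <- size[v]
    if (m == 1L) { kids[[v]] <- integer(0); next }
    i <- sample_split(m, law)
    l <- next_free; r <- next_free + 1L
    next_free <- next_free + 2L
    size[l] <- i; size[r] <- m - i
    kids[[v]] <- c(l, r)
    stack <- c(stack, r, l)         # left popped first: labels left-to-right
  }
  brlen <- if (edge_lengths == "unit") rep(1, n_nodes) else
    rexp(n_nodes, rate = rate)
  brlen[1L] <- planted_length
  labels <- rep(NA_character_, n_nodes)
  labels[size == 1L] <- ""          # filled after postorder renumbering
  tr <- new_planted_tree(kids, brlen, labels, 1L)
  tr$labels <- paste0("t", seq_len(n))
  tr
}

#' Exhaustive distribution over small tree shapes
#'
#' Enumerates every ordered binary shape with `n` leaves (there are
#' `Cat(n-1)` of them) together with its exact probability under the chosen
#' split law, in exact rational arithmetic. Serves as the brute-force oracle
#' for the external-path-length moment recursions.
#'
#' @inheritParams split_pmf
#' @param n number of leaves, at most `max_n`.
#' @param max_n refusal threshold for the enumeration (default 10,
#'   `Cat(9) = 4862` shapes).
#' @return A tibble with columns `shape` (Newick skeleton without lengths),
#'   `p_num`, `p_den` (exact probability numerator/denominator),
#'   `probability`, `epl` (unplanted external path length) and
#'   `sum_sq_depth` (sum of squared unplanted leaf depths).
#' @examples
#' exact_shape_distribution(4, "critical")
#' @export
exact_shape_distribution <- function(n, law = c("critical", "uniform"),
                                     max_n = 10) {
  law <- match.arg(law)
  if (n < 1) stop("`n` must be at least 1")
  if (n > max_n) stop("refusing to enumerate shapes for n > ", max_n)

  q_rat <- function(m, i) {
    if (law == "critical") {
      h <- rat_harmonic(m - 1)
      rat_div(rat(m, 2 * i * (m - i)), h)
    } else {
      cat_r <- function(k) rat(choose(2 * k, k) / (k + 1))
      rat_div(rat_mul(cat_r(i - 1), cat_r(m - i - 1)), cat_r(m - 1))
    }
  }

  memo <- vector("list", n)
  shapes_of <- function(m) {
    if (!is.null(memo[[m]])) return(memo[[m]])
    if (m == 1L) {
      out <- list(list(shape = "*", p = rat(1), epl = 0, ssd = 0))
    } else {
      out <- list()
      for (i in seq_len(m - 1)) {
        qi <- q_rat(m, i)
        for (ls in shapes_of(i)) for (rs in shapes_of(m - i)) {
          out[[length(out) + 1L]] <- list(
            shape = paste0("(", ls$shape, ",", rs$shape, ")"),
            p = rat_mul(qi, rat_mul(ls$p, rs$p)),
            epl = ls$epl + rs$epl + m,
            ssd = ls$ssd + 2 * ls$epl + i + rs$ssd + 2 * rs$epl + (m - i)
          )
        }
      }
    }
    memo[[m]] <<- out
    out
  }
  sh <- shapes_of(n)
  tibble(
    shape = vapply(sh, function(s) s$shape, ""),
    p_num = vapply(sh, function(s) s$p$num, 0),
    p_den = vapply(sh, function(s) s$p$den, 0),
    probability = vapply(sh, function(s) rat_num(s$p), 0),
    epl = vapply(sh, function(s) s$epl, 0),
    sum_sq_depth = vapply(sh, function(s) s$ssd, 0)
  )
}

# Exact moments of EPL and leaf depth from the exhaustive shape distribution.
# Returns rationals; the exchangeability identities E(L) = E(EPL)/n,
# E(L^2) = E(sum d_i^2)/n and E(EPL^2) = n E(L^2) + n(n-1) E(Z) recover the
# per-leaf and pair-product moments.
exact_moments_from_shapes <- function(n, law = c("critical", "uniform")) {
  sh <- exact_shape_distribution(n, law)
  p <- purrr::map2(sh$p_num, sh$p_den, rat)
  wsum <- function(v) rat_sum(purrr::map2(p, v, function(pi, vi)
    rat_mul(pi, rat(vi))))
  epl1 <- wsum(sh$epl)
  epl2 <- wsum(sh$epl^2)
  ssd <- wsum(sh$sum_sq_depth)
  el <- rat_div(epl1, rat(n))
  el2 <- rat_div(ssd, rat(n))
  ez <- if (n >= 2)
    rat_div(rat_sub(epl2, ssd), rat(n * (n - 1))) else rat(0)
  var_epl <- rat_sub(epl2, rat_mul(epl1, epl1))
  list(EL = el, EL2 = el2, EZ = ez, EPL1 = epl1, EPL2 = epl2,
       VarEPL = var_epl)
}
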