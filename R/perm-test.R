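#' Dvoretzky–Kiefer–Wolfowitz resample count
#'
#' Number of resamples needed to estimate an empirical c.d.f. within
#' sup-norm error `epsilon` with probability at least `1 - delta`:
#' `N = ceiling( log(2/delta) / (2 epsilon^2) )`.
#'
#' @param epsilon positive c.d.f. sup-norm tolerance.
#' @param delta failure probability in (0, 1).
#' @return Integer-valued resample count.
#' @examples
#' dkw_sample_size(1e-4, 0.01)  # 264915869
#' @export
dkw_sample_size <- function(epsilon, delta) {
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (delta <= 0 || delta >= 1) stop("`delta` must be in (0, 1)")
  ceiling(log(2 / delta) / (2 * epsilon^2))
}

#' Multivariate hypergeometric resamples
#'
#' Draws `size` independent samples of `k` items without replacement from a
#' pooled count vector, by sequential conditional univariate hypergeometric
#' sampling (one vectorized [stats::rhyper()] call per category, shared
#' across all resamples). Categories with zero pool always get zero; each
#' draw together with its complement partitions the pool exactly.
#'
#' @param size number of resamples.
#' @param pool nonnegative integer vector of pooled category counts.
#' @param k number of items to draw, `0 <= k <= sum(pool)`.
#' @return Integer matrix, `length(pool)` rows by `size` columns.
#' @export
rmultihyper <- function(size, pool, k) {
  if (any(pool < 0)) stop("pool counts must be nonnegative")
  total <- sum(pool)
  if (k < 0 || k > total) stop("`k` must be between 0 and sum(pool)")
  nc <- length(pool)
  out <- matrix(0L, nc, size)
  remaining <- rep.int(as.integer(k), size)
  tail_total <- total
  for (i in seq_len(nc)) {
    tail_total <- tail_total - pool[i]
    if (pool[i] == 0) next
    x <- if (i < nc) rhyper(size, pool[i], tail_total, remaining)
         else remaining
    out[i, ] <- as.integer(x)
    remaining <- remaining - out[i, ]
  }
  out
}

#' Permutation test for Haar-components
#'
#' Tests, split by split, whether the observed Haar-component
#' `lambda_v Delta_v^2` between samples `a` and `b` is larger than expected
#' under the null hypothesis that the two environments are compositionally
#' identical — under which the pooled reads are exchangeable, so resampled
#' pairs are obtained by drawing `|a|` reads without replacement from the
#' pooled counts `a + b` (a multivariate hypergeometric draw), assigning the
#' complement to `b`. One pooled draw services every component, so testing
#' all splits costs no more resamples than testing one.
#'
#' Two p-value conventions are available:
#' * `"add_one"` (default): `p = (1 + #\{stat' >= observed\}) / (N + 1)`,
#'   which can never report zero and guards the degenerate all-tied case;
#' * `"strict"`: `p = #\{stat' > observed\} / N`, floored at `1/N` with
#'   `floor_flag = TRUE` when no resample exceeds the observation — the
#'   "discovery probability" convention for reporting `p < 1/N`.
#'
#' Resampling is streamed in batches: only exceedance counts are kept, never
#' a resample matrix, so memory is `O(n_leaf * batch_size)` whatever `N` is.
#'
#' @param t a `planted_tree`.
#' @param a,b OTU count samples (see [as_abundance()]).
#' @param N number of resamples; when `NULL`, derived from `epsilon` and
#'   `delta` via [dkw_sample_size()].
#' @param epsilon,delta DKW c.d.f. accuracy parameters (used when `N` is
#'   `NULL`).
#' @param alpha significance level recorded alongside the results.
#' @param correction `"benjamini_hochberg"`, `"bonferroni"` or `"none"`.
#' @param m number of hypotheses for the Bonferroni correction; defaults to
#'   the number of tested components.
#' @param comparison `"add_one"` or `"strict"`.
#' @param nodes optional integer vector restricting the test to a subset of
#'   interior node ids (0 = planted root).
#' @param seed optional integer seed.
#' @param batch_size resamples per streamed batch (memory knob only).
#' @param drop_unknown passed to [as_abundance()].
#' @return An object of class `haar_permtest`: list with `results` — tibble
#'   (`node`, `depth`, `n_leaves`, `observed`, `exceedances`, `p_raw`,
#'   `p_adjusted`, `floor_flag`) sorted by decreasing observed component —
#'   plus the test configuration. With a fixed seed the full table is
#'   reproducible bit for bit.
#' @export
haar_perm_test <- function(t, a, b, N = NULL, epsilon = NULL, delta = NULL,
                           alpha = 0.05,
                           correction = c("benjamini_hochberg", "bonferroni",
                                          "none"),
                           m = NULL, comparison = c("add_one", "strict"),
                           nodes = NULL, seed = NULL, batch_size = 2000,
                           drop_unknown = FALSE) {
  stopifnot(inherits(t, "planted_tree"))
  correction <- match.arg(correction)
  comparison <- match.arg(comparison)
  if (is.null(N)) {
    if (is.null(epsilon) || is.null(delta))
      stop("supply `N`, or both `epsilon` and `delta`")
    N <- dkw_sample_size(epsilon, delta)
  }
  if (N < 1) stop("`N` must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)

  a <- as_abundance(a, t, drop_unknown)
  b <- as_abundance(b, t, drop_unknown)
  if (sum(a) <= 0 || sum(b) <= 0) stop("samples must have positive totals")
  tr <- haar_transform(t)
  s <- tr$basis$splits
  lambda <- tr$lambda$lambda[-1L]          # non-root splits, wavelet order

  obs_f <- a / sum(a) - b / sum(b)
  bs <- block_sums(tr$basis, unname(obs_f))
  observed <- lambda * (s$c_minus * bs$left - s$c_plus * bs$right)^2

  pool <- a + b
  na <- sum(a); nb <- sum(b); npool <- na + nb
  exceed <- numeric(length(observed))
  done <- 0
  while (done < N) {
    nres <- min(batch_size, N - done)
    aa <- rmultihyper(nres, unname(pool), na)
    ff <- aa / na - (unname(pool) - aa) / nb    # leaf x resample
    cs <- rbind(0, apply(ff, 2L, cumsum))
    dl <- cs[s$mid + 1L, , drop = FALSE] - cs[s$lo, , drop = FALSE]
    dr <- cs[s$hi + 1L, , drop = FALSE] - cs[s$mid + 1L, , drop = FALSE]
    stat <- lambda * (s$c_minus * dl - s$c_plus * dr)^2
    cmp <- if (comparison == "add_one") stat >= observed else stat > observed
    exceed <- exceed + rowSums(cmp)
    done <- done + nres
  }

  res <- tibble(
    node = s$node,
    depth = s$depth,
    n_leaves = s$n_minus + s$n_plus,
    observed = observed,
    exceedances = exceed
  )
  if (!is.null(nodes)) {
    bad <- setdiff(nodes, c(0L, s$node))
    if (length(bad)) stop("unknown node id(s): ", paste(bad, collapse = ", "))
    res <- res[res$node %in% nodes, ]
  }
  if (comparison == "add_one") {
    res$p_raw <- (1 + res$exceedances) / (N + 1)
    res$floor_flag <- FALSE
  } else {
    res$floor_flag <- res$exceedances == 0
    res$p_raw <- pmax(res$exceedances, 1) / N
  }
  res$p_adjusted <- adjust_pvalues(res$p_raw, method = correction, m = m)
  res <- dplyr::arrange(res, dplyr::desc(.data$observed), .data$node)
  res <- res[, c("node", "depth", "n_leaves", "observed", "exceedances",
                 "p_raw", "p_adjusted", "floor_flag")]

  structure(
    list(results = res, N = N, alpha = alpha, correction = correction,
         comparison = comparison, m = m %||% nrow(res), seed = seed),
    class = "haar_permtest"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.haar_permtest <- function(x, ...) {
  cat("<haar_permtest> N =", x$N, "resamples;", x$correction,
      "correction; comparison =", x$comparison, "\n")
  print(x$results, n = 8)
  invisible(x)
}

#' @rdname haar_perm_test
#' @param x a `haar_permtest` object.
#' @param ... unused.
#' @export
tidy.haar_permtest <- function(x, ...) x$results

#' @rdname haar_perm_test
#' @export
glance.haar_permtest <- function(x, ...) {
  tibble(N = x$N, alpha = x$alpha, correction = x$correction,
         n_components = nrow(x$results),
         n_significant = sum(x$results$p_adjusted <= x$alpha))
}

#' @export
autoplot.haar_permtest <- function(object, ...) {
  df <- object$results
  df$significant <- df$p_adjusted <= object$alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$p_adjusted,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda[v] * Delta[v]^2),
                  y = "adjusted p-value",
                  title = "Component significance") +
    ggplot2::theme_minimal()
}

#' Multiple-testing adjustment of p-values
#'
#' Thin wrapper around [stats::p.adjust()]: Bonferroni with an explicit
#' hypothesis count `m` (`min(1, m p)`) or Benjamini–Hochberg step-up.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"benjamini_hochberg"` or `"none"`.
#' @param m hypothesis count for Bonferroni; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @examples
#' adjust_pvalues(0.001, "bonferroni", m = 12)  # 0.012
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni",
                                         "none"), m = NULL) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  switch(method,
    none = p,
    # min(1, m p); equals p.adjust(..., n = m) whenever m >= length(p), but
    # also supports an explicit m below the vector length (e.g. m = 1)
    bonferroni = pmin(1, (m %||% length(p)) * p),
    benjamini_hochberg = p.adjust(p, method = "BH")
  )
}
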