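#' Exact depth-moment recursions under the critical beta-splitting model
#'
#' Let `L_n` be the edge-depth (unplanted convention, `L_1 = 0`) of a leaf
#' chosen uniformly at random in a critical beta-splitting tree with `n`
#' leaves. Conditioning on the first split of size `(i, n - i)` — the random
#' leaf lands in the size-`i` side with probability `i/n` and its depth is
#' one more than the depth in that subtree — gives the recursions
#' ```
#' E(L_n)   = 1 + (1/h_{n-1}) sum_i E(L_i) / (n - i)
#' E(L_n^2) = 1 + (1/h_{n-1}) sum_i (2 E(L_i) + E(L_i^2)) / (n - i)
#' ```
#' with `h_m` the m-th harmonic number and base `E(L_1) = E(L_1^2) = 0`.
#' The second-moment recursion follows from the same conditional split as the
#' first and is validated in the test suite against the exhaustive
#' small-tree oracle before use. O(N^2) time.
#'
#' @param N largest leaf count.
#' @return A tibble with columns `n`, `EL`, `EL2`.
#' @examples
#' depth_moments_exact(4)$EL  # 0, 1, 5/3, 24/11
#' @export
depth_moments_exact <- function(N) {
  if (N < 1) stop("`N` must be at least 1")
  EL <- EL2 <- numeric(N)
  if (N >= 2) {
    h <- cumsum(1 / seq_len(N))
    for (n in 2:N) {
      i <- seq_len(n - 1)
      w <- 1 / (n - i)
      EL[n] <- 1 + sum(EL[i] * w) / h[n - 1]
      EL2[n] <- 1 + sum((2 * EL[i] + EL2[i]) * w) / h[n - 1]
    }
  }
  tibble(n = seq_len(N), EL = EL, EL2 = EL2)
}

#' Exact pair-product depth moments
#'
#' `E(Z_n) = E(L_{n,1} L_{n,2})`, the expected product of the edge-depths of
#' two distinct leaves after uniform relabelling, via the exact recursion
#' ```
#' E(Z_n) = 2 E(L_n) - 1
#'        + (1/((n-1) h_{n-1})) sum_i ((i - 1)/(n - i)) E(Z_i)
#'        + (1/((n-1) h_{n-1})) sum_i E(L_i) E(L_{n-i})
#' ```
#' with base `E(Z_2) = 1`. O(N^2) time.
#'
#' @param N largest leaf count (at least 2).
#' @param depth optional precomputed [depth_moments_exact()] table.
#' @return A tibble with columns `n` (from 2) and `EZ`.
#' @examples
#' pair_product_exact(3)$EZ  # 1, 8/3
#' @export
pair_product_exact <- function(N, depth = NULL) {
  if (N < 2) stop("`N` must be at least 2")
  if (is.null(depth)) depth <- depth_moments_exact(N)
  EL <- depth$EL
  h <- cumsum(1 / seq_len(N))
  EZ <- numeric(N)
  EZ[2] <- 1
  for (n in seq_len(N)[-(1:2)]) {
    i <- seq_len(n - 1)
    anc <- sum((i - 1) / (n - i) * EZ[i])
    conv <- sum(EL[i] * EL[n - i])
    EZ[n] <- 2 * EL[n] - 1 + (anc + conv) / ((n - 1) * h[n - 1])
  }
  tibble(n = 2:N, EZ = EZ[2:N])
}

#' Exact external-path-length moments
#'
#' Combines the per-leaf recursions with exchangeability:
#' `E(EPL) = n E(L_n)` and
#' `E(EPL^2) = n E(L_n^2) + n (n - 1) E(Z_n)`, whence the variance. All in
#' the unplanted depth convention (`L_1 = 0`).
#'
#' @param N largest leaf count.
#' @return A tibble with columns `n`, `EL`, `EL2`, `EZ`, `EPL1`, `EPL2`,
#'   `VarEPL`.
#' @examples
#' epl_moments_exact(4)[4, ]  # E(EPL) = 96/11, Var = 24/121
#' @export
epl_moments_exact <- function(N) {
  if (N < 1) stop("`N` must be at least 1")
  d <- depth_moments_exact(N)
  EZ <- numeric(N)
  if (N >= 2) EZ[2:N] <- pair_product_exact(N, d)$EZ
  n <- d$n
  EPL1 <- n * d$EL
  EPL2 <- n * d$EL2 + n * (n - 1) * EZ
  tibble(n = n, EL = d$EL, EL2 = d$EL2, EZ = EZ,
         EPL1 = EPL1, EPL2 = EPL2, VarEPL = EPL2 - EPL1^2)
}

# exact-rational version of the recursions, for the small-n oracle tests
depth_pair_moments_rational <- function(N) {
  EL <- EL2 <- EZ <- vector("list", N)
  EL[[1]] <- EL2[[1]] <- rat(0)
  EZ[[1]] <- rat(0)
  if (N >= 2) {
    for (n in 2:N) {
      h <- rat_harmonic(n - 1)
      sL <- sL2 <- sZ <- sC <- rat(0)
      for (i in seq_len(n - 1)) {
        w <- rat(1, n - i)
        sL <- rat_add(sL, rat_mul(EL[[i]], w))
        sL2 <- rat_add(sL2, rat_mul(rat_add(rat_mul(rat(2), EL[[i]]),
                                            EL2[[i]]), w))
        sZ <- rat_add(sZ, rat_mul(rat(i - 1, n - i), EZ[[i]]))
        sC <- rat_add(sC, rat_mul(EL[[i]], EL[[n - i]]))
      }
      EL[[n]] <- rat_add(rat(1), rat_div(sL, h))
      EL2[[n]] <- rat_add(rat(1), rat_div(sL2, h))
      EZ[[n]] <- if (n == 2) rat(1) else
        rat_add(rat_sub(rat_mul(rat(2), EL[[n]]), rat(1)),
                rat_div(rat_add(sZ, sC), rat_mul(rat(n - 1), h)))
    }
  }
  list(EL = EL, EL2 = EL2, EZ = EZ)
}

#' High-precision constants of the asymptotic expansions
#'
#' Riemann zeta values, Euler's constant, and the derived expansion
#' constants: `b0 = gamma^2/(2 zeta2) + gamma zeta3 / zeta2^2 +
#' zeta3^2 / zeta2^3 + 1/10`, plus `C2`, `C1` (second-moment expansion) and
#' `B1` (variance expansion).
#'
#' @return A named list.
#' @export
epl_constants <- function() {
  z2 <- pi^2 / 6
  z3 <- 1.2020569031595942854
  z4 <- pi^4 / 90
  g <- 0.57721566490153286061
  b0 <- g^2 / (2 * z2) + g * z3 / z2^2 + z3^2 / z2^3 + 1 / 10
  C2 <- -9 / (10 * z2) + (3 * g^2 + 4 * z3) / (2 * z2^2) +
    3 * g * z3 / z2^3 + 2 * z3^2 / z2^4
  C1 <- 1 - (9 * g + 20 * z3) / (5 * z2) +
    (5 * g^3 + 20 * z3 * g + 21 * z3 - 30 * z4) / (5 * z2^2) +
    (3 * z3 * g^2 + 4 * z3^2) / z2^3 + 4 * z3^2 * g / z2^4 +
    2 * z3^3 / z2^5
  B1 <- 1 - (2 * g + 4 * z3) / z2 +
    (4 * z3 * g + 4 * z3 - 6 * z4) / z2^2 + 4 * z3^2 / z2^3
  list(zeta2 = z2, zeta3 = z3, zeta4 = z4, gamma = g,
       b0 = b0, C2 = C2, C1 = C1, B1 = B1)
}

#' Coefficients of the asymptotic expansions
#'
#' The expansions, with error terms dropped, are polynomials in `log n`
#' scaled by `n` or `n^2`:
#' * mean EPL: `n [ log^2 n / (2 zeta2) + (gamma zeta2 + zeta3)/zeta2^2
#'   log n + b0 ]`;
#' * second moment: `n^2 [ log^4 n / (4 zeta2^2) +
#'   (gamma zeta2 + zeta3)/zeta2^3 log^3 n + C2 log^2 n + C1 log n ]`;
#' * variance: `n^2 [ (2 zeta3/zeta2^2 - 1/zeta2) log^2 n + B1 log n ]`;
#' * mean depth: the mean-EPL bracket without the `n` factor;
#' * depth variance: `2 zeta3 / (3 zeta2^3) log^3 n`.
#'
#' The mean and second-moment expansions share their two leading
#' coefficients once the mean is squared, which is exactly why they cancel
#' in the variance.
#'
#' @return A tibble with columns `moment` (`"mean_epl"`, `"second_epl"`,
#'   `"var_epl"`, `"mean_depth"`, `"var_depth"`), `n_power`, `log_power`,
#'   `coefficient`.
#' @export
epl_expansion_terms <- function() {
  k <- epl_constants()
  c1 <- (k$gamma * k$zeta2 + k$zeta3) / k$zeta2^2
  dplyr::bind_rows(
    tibble(moment = "mean_epl", n_power = 1, log_power = 2:0,
           coefficient = c(1 / (2 * k$zeta2), c1, k$b0)),
    tibble(moment = "second_epl", n_power = 2, log_power = 4:1,
           coefficient = c(1 / (4 * k$zeta2^2), c1 / k$zeta2, k$C2, k$C1)),
    tibble(moment = "var_epl", n_power = 2, log_power = 2:1,
           coefficient = c(2 * k$zeta3 / k$zeta2^2 - 1 / k$zeta2, k$B1)),
    tibble(moment = "mean_depth", n_power = 0, log_power = 2:0,
           coefficient = c(1 / (2 * k$zeta2), c1, k$b0)),
    tibble(moment = "var_depth", n_power = 0, log_power = 3,
           coefficient = 2 * k$zeta3 / (3 * k$zeta2^3))
  )
}

#' Evaluate the asymptotic moment expansions
#'
#' Evaluates the expansions of [epl_expansion_terms()] at the given leaf
#' counts (error terms dropped).
#'
#' @param n integer vector of leaf counts, each at least 2.
#' @return A tibble with columns `n`, `mean_epl`, `second_epl`, `var_epl`,
#'   `mean_depth`, `var_depth`.
#' @export
epl_moments_asymptotic <- function(n) {
  if (any(n < 2)) stop("`n` must be at least 2")
  terms <- epl_expansion_terms()
  ev <- function(mom, nn) {
    tt <- terms[terms$moment == mom, ]
    vapply(nn, function(x)
      sum(tt$coefficient * x^tt$n_power * log(x)^tt$log_power), 0)
  }
  tibble(n = n,
         mean_epl = ev("mean_epl", n),
         second_epl = ev("second_epl", n),
         var_epl = ev("var_epl", n),
         mean_depth = ev("mean_depth", n),
         var_depth = ev("var_depth", n))
}

#' Monte-Carlo external-path-length moments
#'
#' Simulates trees from the chosen ensemble and reports sample mean and
#' variance of the (unplanted) external path length with standard errors.
#'
#' @inheritParams sample_tree
#' @param reps number of simulated trees (at least 2).
#' @return A one-row tibble: `n`, `reps`, `mean`, `se_mean`, `var`,
#'   `se_var`.
#' @export
monte_carlo_epl <- function(n, law = c("critical", "uniform"), reps = 200,
                            seed = NULL) {
  law <- match.arg(law)
  if (reps < 2) stop("`reps` must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  epl <- vapply(seq_len(reps), function(r)
    external_path_length(sample_tree(n, law)), 0)
  m <- mean(epl); v <- var(epl)
  m4 <- mean((epl - m)^4)
  tibble(n = n, reps = reps, mean = m, se_mean = sqrt(v / reps),
         var = v, se_var = sqrt(pmax(m4 - v^2, 0) / reps))
}

#' Compare exact and asymptotic external-path-length moments
#'
#' Relative error of the asymptotic expansions against the exact recursion
#' values, on a log-log scale.
#'
#' @param n integer vector of leaf counts (each at least 2).
#' @return A ggplot object.
#' @export
plot_epl_moments <- function(n = 2^(6:12)) {
  ex <- epl_moments_exact(max(n))[n, ]
  as <- epl_moments_asymptotic(n)
  df <- dplyr::bind_rows(
    tibble(n = n, moment = "mean",
           rel_error = abs(ex$EPL1 - as$mean_epl) / ex$EPL1),
    tibble(n = n, moment = "second moment",
           rel_error = abs(ex$EPL2 - as$second_epl) / ex$EPL2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$rel_error,
                                   colour = .data$moment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "leaves n", y = "relative error",
                  title = "Asymptotic expansions vs exact recursions") +
    ggplot2::theme_minimal()
}
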