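#' Haar-like wavelet basis of a planted binary tree
#'
#' One wavelet per interior node of the planted tree. The root wavelet is the
#' constant `1/sqrt(n)`. Every other interior node `v` contributes a
#' piecewise-constant, zero-sum, unit-norm vector, positive on the leaves of
#' the left subtree `L(v-)` with value
#' `c_minus = sqrt(|L(v+)| / (|L(v-)| |L(v)|))` and negative on the right
#' subtree `L(v+)` with value `-c_plus = -sqrt(|L(v-)| / (|L(v+)| |L(v)|))`.
#' Because leaves are numbered left-to-right, each support block is a
#' contiguous leaf-rank interval; the basis is stored as those intervals plus
#' the two coefficients — never as a dense matrix.
#'
#' @param t a `planted_tree`.
#' @return An object of class `haar_basis`: list with `n_leaf`, `root_coef`
#'   (`1/sqrt(n)`) and `splits`, a tibble with one row per non-root interior
#'   node: `node` (postorder id), `depth`, `lo`, `mid`, `hi` (leaf-rank
#'   interval; left block `lo..mid`, right block `mid+1..hi`), `n_minus`,
#'   `n_plus`, `c_minus`, `c_plus`.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' as.matrix(haar_basis(tr))
#' @export
haar_basis <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  internal <- which(!t$is_leaf)
  d <- node_depths(t)
  if (length(internal)) {
    left <- t$kids[internal, 1L]
    right <- t$kids[internal, 2L]
    nm <- t$n_desc[left]
    np <- t$n_desc[right]
    nv <- nm + np
    splits <- tibble(
      node = internal,
      depth = d[internal] + 1L,      # edge-depth below the planted root o
      lo = t$lo[internal], mid = t$hi[left], hi = t$hi[internal],
      n_minus = nm, n_plus = np,
      c_minus = sqrt(np / (nm * nv)), c_plus = sqrt(nm / (np * nv))
    )
  } else {
    splits <- tibble(node = integer(), depth = integer(), lo = integer(),
                     mid = integer(), hi = integer(), n_minus = integer(),
                     n_plus = integer(), c_minus = numeric(),
                     c_plus = numeric())
  }
  structure(list(n_leaf = t$n_leaf, root_coef = 1 / sqrt(t$n_leaf),
                 splits = splits, leaf_label = t$labels),
            class = "haar_basis")
}

#' @export
print.haar_basis <- function(x, ...) {
  cat("<haar_basis> ", x$n_leaf, " wavelets on ", x$n_leaf, " leaves\n",
      sep = "")
  print(x$splits, n = 5)
  invisible(x)
}

# wavelet column order used everywhere: planted root o first (id 0), then
# non-root interior nodes by ascending postorder id
wavelet_nodes <- function(basis) c(0L, basis$splits$node)

#' Materialize the Haar-like basis matrix
#'
#' Dense `n x n` orthonormal matrix `Phi`; columns are ordered with the
#' planted-root (constant) wavelet first, then non-root interior nodes by
#' ascending postorder id. Intended for small trees and oracle checks.
#'
#' @param x a `haar_basis`.
#' @param ... unused.
#' @return A numeric matrix with leaf labels as rownames and wavelet node ids
#'   (0 for the planted root) as colnames.
#' @export
as.matrix.haar_basis <- function(x, ...) {
  n <- x$n_leaf
  phi <- matrix(0, n, n)
  phi[, 1L] <- x$root_coef
  s <- x$splits
  for (k in seq_len(nrow(s))) {
    phi[s$lo[k]:s$mid[k], k + 1L] <- s$c_minus[k]
    phi[(s$mid[k] + 1L):s$hi[k], k + 1L] <- -s$c_plus[k]
  }
  dimnames(phi) <- list(x$leaf_label, wavelet_nodes(x))
  phi
}

#' Dense ultrametric covariance matrix of a planted tree
#'
#' `C(i, j)` is the total length of the edges from the least common ancestor
#' of leaves `i` and `j` up to the planted root, inclusive of the planted
#' edge; `C(i, i)` is the weighted planted depth of leaf `i`. The matrix is
#' ultrametric and positive semidefinite. Only intended for small trees — the
#' sparse path ([haar_transform()]) never materializes it.
#'
#' @param t a `planted_tree`.
#' @param max_leaves refuse to materialize beyond this many leaves
#'   (default 2048).
#' @return A symmetric numeric matrix with leaf labels as dimnames.
#' @export
covariance_dense <- function(t, max_leaves = 2048) {
  stopifnot(inherits(t, "planted_tree"))
  n <- t$n_leaf
  if (n > max_leaves)
    stop("tree has ", n, " > ", max_leaves,
         " leaves; use haar_transform() for the sparse path")
  pl <- node_path_lengths(t)
  C <- matrix(0, n, n)
  diag(C) <- pl[t$leaf_ids]
  for (v in which(!t$is_leaf)) {
    lblk <- t$lo[v]:t$hi[t$kids[v, 1L]]
    rblk <- (t$hi[t$kids[v, 1L]] + 1L):t$hi[v]
    C[lblk, rblk] <- pl[v]
    C[rblk, lblk] <- pl[v]
  }
  dimnames(C) <- list(t$labels, t$labels)
  C
}

#' Haar-like transform of the phylogenetic covariance matrix
#'
#' Computes `Phi^T C Phi` for the tree's ultrametric covariance `C` without
#' ever materializing `C`, in `O(n + #structural pairs)` time. A single
#' postorder pass accumulates the subtree second moments
#' `S(w) = sum of l(e) |L(e)|^2` over the edges in the subtree of `w`
#' including `w`'s parent edge; then
#' * diagonal: `lambda_v = c_minus^2 S(v-) + c_plus^2 S(v+)`, and for the
#'   planted root `lambda_o = S(top)/n` (the sum runs over every edge
#'   including the planted one);
#' * off-diagonal: the entry for an ancestor wavelet `u` and descendant `v`
#'   is the (constant) value of `phi_u` on the block containing `L(v)` times
#'   `c_minus(v) S(v-) - c_plus(v) S(v+)`; every other pair is structurally
#'   zero because the supports are disjoint.
#'
#' @param t a `planted_tree`.
#' @return An object of class `haar_transform`: list with `n` (matrix order,
#'   equal to the number of leaves), `lambda` — tibble (`node` with 0 for the
#'   planted root, `depth`, `n_leaves`, `lambda`) in wavelet order — and
#'   `offdiag` — tibble (`u`, `v`, `value`) over the structurally nonzero
#'   pairs with `u` the ancestor, sorted by `(u, v)`; the symmetric mirror is
#'   implied.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' haar_transform(tr)$lambda
#' @export
haar_transform <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  n <- t$n_leaf
  n_nodes <- 2L * n - 1L
  basis <- haar_basis(t)
  d <- node_depths(t)

  S <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    below <- if (t$is_leaf[v]) 0 else S[t$kids[v, 1L]] + S[t$kids[v, 2L]]
    S[v] <- below + t$brlen[v] * t$n_desc[v]^2
  }

  s <- basis$splits
  lambda_root <- S[t$root] / n
  if (nrow(s)) {
    Sm <- S[t$kids[s$node, 1L]]
    Sp <- S[t$kids[s$node, 2L]]
    lam <- s$c_minus^2 * Sm + s$c_plus^2 * Sp
    tv <- s$c_minus * Sm - s$c_plus * Sp      # shared off-diagonal factor
  } else {
    lam <- numeric(0); tv <- numeric(0)
  }
  lambda <- tibble(
    node = c(0L, s$node),
    depth = c(0L, s$depth),
    n_leaves = c(n, s$n_minus + s$n_plus),
    lambda = c(lambda_root, lam)
  )

  # structural pairs: walk each non-root interior node up to o
  row_of <- integer(n_nodes)                 # node id -> row in `s`
  row_of[s$node] <- seq_len(nrow(s))
  total_pairs <- sum(d[s$node] + 1L)         # interior ancestors plus o
  us <- integer(total_pairs); vs <- integer(total_pairs)
  vals <- numeric(total_pairs)
  p <- 0L
  for (k in seq_len(nrow(s))) {
    v <- s$node[k]
    w <- v
    u <- t$parent[w]
    while (!is.na(u)) {
      ku <- row_of[u]
      sign_val <- if (t$kids[u, 1L] == w) s$c_minus[ku] else -s$c_plus[ku]
      p <- p + 1L
      us[p] <- u; vs[p] <- v; vals[p] <- sign_val * tv[k]
      w <- u
      u <- t$parent[w]
    }
    p <- p + 1L
    us[p] <- 0L; vs[p] <- v; vals[p] <- basis$root_coef * tv[k]
  }
  offdiag <- tibble(u = us, v = vs, value = vals) |>
    dplyr::arrange(.data$u, .data$v)

  structure(list(n = n, lambda = lambda, offdiag = offdiag, basis = basis),
            class = "haar_transform")
}

#' @export
print.haar_transform <- function(x, ...) {
  np <- nrow(x$offdiag)
  cat("<haar_transform> order ", x$n, "; ", np,
      " structural off-diagonal pairs (upper half)\n", sep = "")
  print(x$lambda, n = 5)
  invisible(x)
}

# wavelet index (1..n, root first) of transform node ids
transform_index <- function(x, nodes) match(nodes, x$lambda$node)

#' Materialize the transformed matrix
#'
#' Dense symmetric `Phi^T C Phi` in wavelet order (planted root first, then
#' interior nodes by ascending postorder id). For oracle checks on small
#' trees.
#'
#' @param x a `haar_transform`.
#' @param ... unused.
#' @return A symmetric numeric matrix with wavelet node ids as dimnames.
#' @export
as.matrix.haar_transform <- function(x, ...) {
  n <- x$n
  M <- matrix(0, n, n)
  diag(M) <- x$lambda$lambda
  i <- transform_index(x, x$offdiag$u)
  j <- transform_index(x, x$offdiag$v)
  M[cbind(i, j)] <- x$offdiag$value
  M[cbind(j, i)] <- x$offdiag$value
  dimnames(M) <- list(x$lambda$node, x$lambda$node)
  M
}

#' Sparsity statistics of a Haar-like transform
#'
#' Fraction `xi` of vanishing entries of `Phi^T C Phi`. In `"structural"`
#' mode a pair counts as vanishing when the two wavelet supports are
#' disjoint (the entry is then exactly zero regardless of edge lengths); in
#' `"numerical"` mode stored structural entries with `|value| <= tol` count
#' as vanishing too. Reported over off-diagonal entries (denominator
#' `n^2 - n`) and over all entries (denominator `n^2`).
#'
#' @param x a `haar_transform`.
#' @param mode `"structural"` or `"numerical"`.
#' @param tol magnitude threshold for numerical zeros (default `1e-12`).
#' @return A one-row tibble: `mode`, `n`, `offdiag_pairs`, `vanishing`,
#'   `xi_offdiag`, `xi_all`.
#' @export
sparsity_stats <- function(x, mode = c("structural", "numerical"),
                           tol = 1e-12) {
  stopifnot(inherits(x, "haar_transform"))
  mode <- match.arg(mode)
  if (tol < 0) stop("`tol` must be nonnegative")
  n <- x$n
  total_off <- n^2 - n
  nonzero <- 2 * nrow(x$offdiag)            # both triangles
  if (mode == "numerical")
    nonzero <- 2 * sum(abs(x$offdiag$value) > tol)
  vanish <- total_off - nonzero
  tibble(mode = mode, n = n, offdiag_pairs = total_off, vanishing = vanish,
         xi_offdiag = if (total_off > 0) vanish / total_off else 1,
         xi_all = if (n > 0) (vanish + sum(abs(x$lambda$lambda) <= tol &
                                             mode == "numerical")) / n^2
                  else 1)
}

#' Guaranteed sparsification bound
#'
#' Upper bound on the fraction `1 - xi` of structurally nonzero off-diagonal
#' entries of `Phi^T C Phi`:
#' `1 - xi <= 2 (EPL(T) + 1) / n^2 - 3 / n`,
#' with the external path length taken in the planted convention. Values at
#' or above 1 make the bound vacuous (e.g. caterpillar trees).
#'
#' @param t a `planted_tree` with at least 2 leaves.
#' @return A single number.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' sparsity_bound(tr)  # 0.875
#' @export
sparsity_bound <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  if (t$n_leaf < 2) stop("`t` must have at least 2 leaves")
  n <- t$n_leaf
  epl <- external_path_length(t, planted = TRUE)
  2 * (epl + 1) / n^2 - 3 / n
}

#' Write a Haar-like transform to Matrix Market + TSV
#'
#' The off-diagonal structural entries are written as a symmetric coordinate
#' Matrix Market file in wavelet order (planted root first, then interior
#' nodes by postorder rank) and the diagonal as a TSV
#' (`node`, `depth`, `n_leaves`, `lambda`).
#'
#' @param x a `haar_transform`.
#' @param mtx_file path for the Matrix Market file.
#' @param diag_file path for the diagonal TSV.
#' @param mode,tol passed to the entry filter: `"numerical"` drops stored
#'   entries with `|value| <= tol`.
#' @return Invisibly, the sparse [Matrix::sparseMatrix] that was written
#'   (diagonal included).
#' @export
write_transform <- function(x, mtx_file, diag_file = NULL,
                            mode = c("structural", "numerical"),
                            tol = 1e-12) {
  stopifnot(inherits(x, "haar_transform"))
  mode <- match.arg(mode)
  od <- x$offdiag
  if (mode == "numerical") od <- od[abs(od$value) > tol, ]
  iu <- transform_index(x, od$u)
  jv <- transform_index(x, od$v)
  i <- pmin(iu, jv)               # ancestors sit later in postorder: flip
  j <- pmax(iu, jv)               # into the upper triangle for storage
  M <- Matrix::sparseMatrix(
    i = c(i, seq_len(x$n)), j = c(j, seq_len(x$n)),
    x = c(od$value, x$lambda$lambda), dims = c(x$n, x$n), symmetric = TRUE
  )
  Matrix::writeMM(M, mtx_file)
  if (!is.null(diag_file))
    readr::write_tsv(x$lambda, diag_file)
  invisible(M)
}

#' Sparsity pattern plot
#'
#' Tile plot of the structurally nonzero entries of the transformed matrix,
#' in wavelet order. Dark tiles mark the stored (structural) entries; the
#' diagonal is always present.
#'
#' @param object a `haar_transform`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.haar_transform <- function(object, ...) {
  i <- transform_index(object, object$offdiag$u)
  j <- transform_index(object, object$offdiag$v)
  df <- tibble(row = c(i, j, seq_len(object$n)),
               col = c(j, i, seq_len(object$n)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "wavelet", y = "wavelet",
                  title = "Structural sparsity pattern of ΦᵀCΦ") +
    ggplot2::theme_minimal()
}
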