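#' Coerce OTU counts to a leaf-ordered abundance vector
#'
#' Microbial samples are leaf-indexed nonnegative integer count vectors. This
#' helper accepts a named vector or a two-column data frame (`otu`, `count`)
#' and returns counts aligned to the tree's left-to-right leaf order. OTUs
#' absent from the sample get count 0. By default, OTU names absent from the
#' tree are an error (strict mode); with `drop_unknown = TRUE` they are
#' dropped with a message.
#'
#' @param x named numeric vector, or data frame with columns `otu` and
#'   `count` (or any single count column next to `otu`).
#' @param t a `planted_tree`.
#' @param drop_unknown drop OTUs not found among the tree's leaves instead of
#'   erroring.
#' @return Numeric vector of length `n_leaf`, named by leaf label.
#' @export
as_abundance <- function(x, t, drop_unknown = FALSE) {
  stopifnot(inherits(t, "planted_tree"))
  if (is.data.frame(x)) {
    if (!"otu" %in% names(x)) stop("data-frame input needs an `otu` column")
    cnt_col <- setdiff(names(x), "otu")
    if (length(cnt_col) != 1L)
      stop("data-frame input needs exactly one count column")
    x <- setNames(x[[cnt_col]], x$otu)
  }
  if (is.null(names(x))) {
    if (length(x) != t$n_leaf)
      stop("unnamed counts must have one entry per leaf")
    names(x) <- t$labels
  }
  if (any(x < 0)) stop("counts must be nonnegative")
  unknown <- setdiff(names(x), t$labels)
  if (length(unknown)) {
    if (!drop_unknown)
      stop(length(unknown), " OTU(s) not found in the tree (first: ",
           unknown[1], "); set drop_unknown = TRUE to drop them")
    message("dropping ", length(unknown), " OTU(s) absent from the tree")
    x <- x[!names(x) %in% unknown]
  }
  out <- setNames(numeric(t$n_leaf), t$labels)
  out[names(x)] <- x
  out
}

# bottom-up subtree sums of a leaf-rank-ordered vector: for each non-root
# interior node, the sums over the left and right blocks, via one cumsum
block_sums <- function(basis, f) {
  cs <- c(0, cumsum(f))
  s <- basis$splits
  list(left = cs[s$mid + 1L] - cs[s$lo],
       right = cs[s$hi + 1L] - cs[s$mid + 1L],
       total = cs[length(cs)])
}

#' Haar-like coordinates of a leaf-indexed vector
#'
#' Coordinates `Delta_v = phi_v^T f` of `f` in the Haar-like basis, computed
#' in O(n) total via one cumulative-sum pass over the leaf order (each
#' coordinate is a two-block contrast), not by dense dot products.
#'
#' @param basis a `haar_basis`.
#' @param f numeric vector over leaves in leaf-rank order (or named by leaf
#'   label; missing leaves count as 0).
#' @return A tibble with columns `node` (0 for the planted root) and `delta`,
#'   in wavelet order.
#' @export
haar_coordinates <- function(basis, f) {
  stopifnot(inherits(basis, "haar_basis"))
  if (!is.null(names(f))) {
    ff <- setNames(numeric(basis$n_leaf), basis$leaf_label)
    ff[intersect(names(f), basis$leaf_label)] <-
      f[intersect(names(f), basis$leaf_label)]
    f <- ff
  }
  if (length(f) != basis$n_leaf) stop("`f` must have one entry per leaf")
  bs <- block_sums(basis, f)
  s <- basis$splits
  tibble(node = wavelet_nodes(basis),
         delta = c(basis$root_coef * bs$total,
                   s$c_minus * bs$left - s$c_plus * bs$right))
}

#' Haar-like distance between two microbial samples
#'
#' The Haar-like distance is
#' `d_h(a, b) = sqrt( sum_v lambda_v Delta_v^2 )` over the interior nodes of
#' the reference tree, where `lambda_v` is the diagonal of the Haar-like
#' transform of the tree's covariance matrix and
#' `Delta_v = phi_v^T (a/|a| - b/|b|)`. Each summand `lambda_v Delta_v^2` is
#' the *Haar-component* of split `v`: a large component flags a split whose
#' two sides differ in relative abundance between the environments, which is
#' what makes this beta-diversity metric interpretable. Only the diagonal
#' `lambda_v` enters the definition, by construction, even on trees whose
#' transform has nonzero off-diagonal entries.
#'
#' @param t a `planted_tree`.
#' @param a,b OTU count samples (see [as_abundance()]); totals must be
#'   positive.
#' @param transform optionally a precomputed [haar_transform()] of `t`.
#' @param drop_unknown passed to [as_abundance()].
#' @return An object of class `haar_dist`: list with `distance`, and
#'   `components` — a tibble (`node`, `depth`, `n_leaves`, `delta`,
#'   `component`) ranked by decreasing component (ties broken by postorder
#'   node id). The planted-root component is always 0 because relative
#'   abundances subtract to a zero-sum vector.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' d <- haar_distance(tr, c(A = 4), c(C = 2, D = 2))
#' d$distance^2  # 3.5
#' @export
haar_distance <- function(t, a, b, transform = NULL, drop_unknown = FALSE) {
  stopifnot(inherits(t, "planted_tree"))
  a <- as_abundance(a, t, drop_unknown)
  b <- as_abundance(b, t, drop_unknown)
  if (sum(a) <= 0 || sum(b) <= 0) stop("samples must have positive totals")
  if (is.null(transform)) transform <- haar_transform(t)
  f <- a / sum(a) - b / sum(b)
  co <- haar_coordinates(transform$basis, unname(f))
  comp <- transform$lambda |>
    dplyr::left_join(co, by = "node") |>
    dplyr::mutate(component = .data$lambda * .data$delta^2) |>
    dplyr::arrange(dplyr::desc(.data$component), .data$node)
  structure(
    list(distance = sqrt(sum(comp$component)), components = comp,
         f = setNames(f, t$labels), n_a = sum(a), n_b = sum(b)),
    class = "haar_dist"
  )
}

#' @export
print.haar_dist <- function(x, ...) {
  cat("<haar_dist> d_h =", format(x$distance), "\n")
  cat("top components:\n")
  print(x$components, n = 5)
  invisible(x)
}

#' @rdname haar_distance
#' @param x a `haar_dist` object.
#' @param ... unused.
#' @export
tidy.haar_dist <- function(x, ...) x$components

#' @rdname haar_distance
#' @export
glance.haar_dist <- function(x, ...) {
  tibble(distance = x$distance,
         n_components = nrow(x$components),
         n_nonzero = sum(x$components$component > 0),
         total_a = x$n_a, total_b = x$n_b)
}

#' @export
autoplot.haar_dist <- function(object, top = 20, ...) {
  df <- head(object$components, top)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$node)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(lambda[v] * Delta[v]^2), y = "split (node)",
                  title = "Haar-components of the distance") +
    ggplot2::theme_minimal()
}

#' Reconstruction from a subset of Haar coordinates
#'
#' Projects the kept coordinates back to the leaf basis:
#' `delta_tilde = sum_{v in keep} Delta_v phi_v`, computed sparsely in
#' `O(sum of kept support sizes)`. Keeping the significant components only
#' yields a denoised proxy for the relative-abundance difference between two
#' environments.
#'
#' @param basis a `haar_basis`.
#' @param coords tibble from [haar_coordinates()] (columns `node`, `delta`).
#' @param keep integer vector of interior node ids to keep (0 = planted
#'   root).
#' @return A tibble with columns `leaf`, `label`, `value`.
#' @export
filtered_reconstruction <- function(basis, coords, keep) {
  stopifnot(inherits(basis, "haar_basis"))
  bad <- setdiff(keep, wavelet_nodes(basis))
  if (length(bad)) stop("unknown interior node(s): ", paste(bad, collapse = ", "))
  out <- numeric(basis$n_leaf)
  delta <- setNames(coords$delta, coords$node)
  if (0L %in% keep)
    out <- out + basis$root_coef * delta[["0"]]
  s <- basis$splits
  for (k in which(s$node %in% setdiff(keep, 0L))) {
    dv <- delta[[as.character(s$node[k])]]
    out[s$lo[k]:s$mid[k]] <- out[s$lo[k]:s$mid[k]] + dv * s$c_minus[k]
    out[(s$mid[k] + 1L):s$hi[k]] <- out[(s$mid[k] + 1L):s$hi[k]] -
      dv * s$c_plus[k]
  }
  tibble(leaf = seq_len(basis$n_leaf), label = basis$leaf_label, value = out)
}

#' Aggregate a leaf-indexed difference by group
#'
#' Plain per-group sums of `f` (e.g. taxonomic classes under a split):
#' positive values indicate prevalence in the first sample. When the groups
#' are the two child blocks of a split `v`, the difference of the group
#' means is proportional to the Haar coordinate `Delta_v`.
#'
#' @param f leaf-indexed numeric vector (leaf-rank order or named by label).
#' @param groups named character/factor vector mapping leaf labels (or
#'   leaf-rank names) to group labels; leaves absent from `groups` are
#'   ignored.
#' @return A tibble with columns `group` and `total`.
#' @export
grouped_difference <- function(f, groups) {
  if (is.null(names(groups))) stop("`groups` must be named by leaf")
  if (is.null(names(f)))
    names(f) <- as.character(seq_along(f))
  common <- intersect(names(groups), names(f))
  tibble(group = as.character(groups[common]), value = f[common]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(total = sum(.data$value), .groups = "drop")
}

#' Read an OTU count table
#'
#' Tab-separated table with a leading `otu_id` column and one integer count
#' column per sample.
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_otu_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  names(tb)[1] <- "otu_id"
  tb
}

#' Extract one sample column of an OTU table as counts
#'
#' @param table tibble from [read_otu_table()].
#' @param sample column name.
#' @return Named numeric vector of counts.
#' @export
otu_sample <- function(table, sample) {
  if (!sample %in% names(table)) stop("no sample column `", sample, "`")
  setNames(table[[sample]], table$otu_id)
}
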