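#' Planted binary trees
#'
#' A *planted* tree is a rooted tree whose root `o` has degree one; the single
#' edge below it (the "planted edge") contributes shared covariance to every
#' leaf. `treehaar` stores the binary part of the tree in arrays indexed by
#' postorder rank (children before parents, left before right), so that leaves
#' are numbered `1..n` in their left-to-right order and the top binary node has
#' the largest index `2n - 1`. The planted root is kept implicit: its edge
#' length is the `brlen` entry of the top node.
#'
#' Multifurcations are resolved on input into a left-to-right cascade of
#' zero-length edges, which leaves the ultrametric covariance matrix of the
#' tree unchanged while making every interior node strictly binary.
#'
#' @param kids list over raw node ids of integer child-id vectors (leaves:
#'   empty), in left-to-right order; multifurcations allowed.
#' @param brlen numeric vector of edge lengths to the parent; the root entry is
#'   the planted-edge length.
#' @param labels character labels for leaf nodes (`NA` elsewhere).
#' @param root raw id of the top node.
#' @return An object of class `planted_tree`: a list with fields `n_leaf`,
#'   `parent`, `kids` (two-column matrix, `NA` rows for leaves), `brlen`,
#'   `is_leaf`, `leaf_rank`, `leaf_ids`, `labels`, `lo`, `hi` (leaf-rank
#'   interval spanned by each node), `n_desc` (descendant leaf counts) and
#'   `root`.
#' @keywords internal
new_planted_tree <- function(kids, brlen, labels, root) {
  stopifnot(length(kids) == length(brlen), length(brlen) == length(labels))
  if (any(brlen < 0, na.rm = TRUE)) stop("edge lengths must be nonnegative")

  # resolve multifurcations: (c1, c2, ..., ck) -> (c1, new) with new = (c2..ck)
  i <- 1L
  while (i <= length(kids)) {
    ch <- kids[[i]]
    if (length(ch) > 2L) {
      new_id <- length(kids) + 1L
      kids[[new_id]] <- ch[-1L]
      brlen[new_id] <- 0
      labels[new_id] <- NA_character_
      kids[[i]] <- c(ch[1L], new_id)
    } else {
      i <- i + 1L
    }
  }
  if (any(lengths(kids) == 1L & seq_along(kids) != root))
    stop("interior nodes must have at least two children")
  if (length(kids[[root]]) == 1L) stop("top node must be a leaf or binary")

  # iterative postorder (left before right): reverse of node/right/left preorder
  n_nodes <- sum(lengths(kids) > 0L) * 0L  # placeholder
  stack <- c(root)
  out <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[v]]
    if (length(ch)) stack <- c(stack, ch)  # left pushed first => popped last
  }
  post <- rev(out)
  n_nodes <- length(post)
  rank_of <- integer(length(kids))
  rank_of[post] <- seq_len(n_nodes)

  is_leaf <- lengths(kids)[post] == 0L
  n_leaf <- sum(is_leaf)
  if (n_nodes != 2L * n_leaf - 1L) stop("tree is not binary after resolution")

  parent <- rep(NA_integer_, n_nodes)
  km <- matrix(NA_integer_, n_nodes, 2L)
  for (v in seq_len(n_nodes)) {
    ch <- kids[[post[v]]]
    if (length(ch)) {
      km[v, ] <- rank_of[ch]
      parent[rank_of[ch]] <- v
    }
  }

  leaf_ids <- which(is_leaf)            # increasing postorder = left-to-right
  leaf_rank <- integer(n_nodes)
  leaf_rank[leaf_ids] <- seq_len(n_leaf)

  lo <- hi <- integer(n_nodes)
  n_desc <- integer(n_nodes)
  for (v in seq_len(n_nodes)) {          # postorder: children precede parents
    if (is_leaf[v]) {
      lo[v] <- hi[v] <- leaf_rank[v]
      n_desc[v] <- 1L
    } else {
      lo[v] <- lo[km[v, 1L]]
      hi[v] <- hi[km[v, 2L]]
      n_desc[v] <- n_desc[km[v, 1L]] + n_desc[km[v, 2L]]
    }
  }

  structure(
    list(
      n_leaf = n_leaf, parent = parent, kids = km,
      brlen = as.numeric(brlen[post]), is_leaf = is_leaf,
      leaf_rank = leaf_rank, leaf_ids = leaf_ids,
      labels = labels[post][leaf_ids],
      lo = lo, hi = hi, n_desc = n_desc, root = n_nodes
    ),
    class = "planted_tree"
  )
}

#' Read a planted binary tree from Newick
#'
#' Parses a Newick string (or file) into a [planted_tree][new_planted_tree].
#' Branch lengths are optional and default to 1; a branch length on the root,
#' when present, becomes the planted-edge length, otherwise
#' `default_planted_length` is used. Multifurcations are resolved into a
#' left-to-right cascade of zero-length edges.
#'
#' @param text Newick string (mutually exclusive with `file`).
#' @param file path to a Newick file.
#' @param default_planted_length planted-edge length used when the Newick root
#'   carries no branch length. Default 0.
#' @return A `planted_tree`.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' tr
#' @export
read_planted_tree <- function(text = NULL, file = NULL,
                              default_planted_length = 0) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text) || text == ";") stop("empty Newick tree")
  if (default_planted_length < 0) stop("planted length must be nonnegative")

  # single-leaf trees ("A:1;"): ape cannot represent them
  if (!grepl("(", text, fixed = TRUE)) {
    m <- regmatches(text, regexec("^([^:;,()]+)(:([0-9eE.+-]+))?;?$", text))[[1]]
    if (length(m) == 0L || !nzchar(m[2]))
      stop("malformed Newick string: ", text)
    len <- if (nzchar(m[4])) as.numeric(m[4]) else default_planted_length
    return(new_planted_tree(list(integer(0)), len, m[2], 1L))
  }

  ph <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick string: ", conditionMessage(w))
  )
  if (is.null(ph) || !inherits(ph, "phylo"))
    stop("malformed Newick string")
  as_planted_tree(ph, default_planted_length = default_planted_length)
}

#' Convert an ape `phylo` tree to a planted tree
#'
#' Child order follows the edge-row order of the `phylo` object (the order in
#' which clades appear in the Newick source for trees read with
#' [ape::read.tree()]). A `root.edge`, when present, becomes the planted edge.
#' Missing branch lengths default to 1.
#'
#' @param ph an [ape::phylo] object.
#' @inheritParams read_planted_tree
#' @return A `planted_tree`.
#' @export
as_planted_tree <- function(ph, default_planted_length = 0) {
  stopifnot(inherits(ph, "phylo"))
  n_tip <- length(ph$tip.label)
  n_all <- n_tip + ph$Nnode
  kids <- vector("list", n_all)
  for (v in seq_len(n_all)) kids[[v]] <- integer(0)
  for (r in seq_len(nrow(ph$edge))) {
    p <- ph$edge[r, 1L]
    kids[[p]] <- c(kids[[p]], ph$edge[r, 2L])
  }
  brlen <- rep(1, n_all)
  if (!is.null(ph$edge.length)) {
    el <- ph$edge.length
    el[is.na(el)] <- 1
    brlen[ph$edge[, 2L]] <- el
  }
  root <- n_tip + 1L
  brlen[root] <- if (!is.null(ph$root.edge)) ph$root.edge else
    default_planted_length
  labels <- rep(NA_character_, n_all)
  labels[seq_len(n_tip)] <- ph$tip.label
  new_planted_tree(kids, brlen, labels, root)
}

#' Convert a planted tree to an ape `phylo` object
#'
#' The planted-edge length is stored in the `root.edge` field. Useful for
#' plotting and interoperating with the wider phylogenetics ecosystem.
#'
#' @param t a `planted_tree`.
#' @return An [ape::phylo] object.
#' @export
as_phylo <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  n <- t$n_leaf
  if (n == 1L) stop("ape cannot represent single-leaf trees")
  # ape numbering: tips 1..n, internals n+1..2n-1 with root = n+1 (preorder)
  internal <- which(!t$is_leaf)
  # assign ape ids: internals in reverse postorder (preorder) get n+1, n+2, ...
  ape_id <- integer(2L * n - 1L)
  ape_id[t$leaf_ids] <- t$leaf_rank[t$leaf_ids]
  ape_id[rev(internal)] <- n + seq_along(internal)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  r <- 0L
  for (v in rev(seq_len(2L * n - 1L))) {   # preorder-ish fill
    if (t$is_leaf[v]) next
    for (c in t$kids[v, ]) {
      r <- r + 1L
      edge[r, ] <- c(ape_id[v], ape_id[c])
      elen[r] <- t$brlen[c]
    }
  }
  ph <- structure(
    list(edge = edge, edge.length = elen, Nnode = n - 1L,
         tip.label = t$labels, root.edge = t$brlen[t$root]),
    class = "phylo", order = "cladewise"
  )
  ph
}

#' Write a planted tree as Newick
#'
#' The planted-edge length is emitted as the root branch length, so
#' write-then-read round-trips preserve topology, branch lengths (to the
#' printed precision of 10 significant digits) and leaf order.
#'
#' @param t a `planted_tree`.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `file`.
#' @export
write_planted_tree <- function(t, file = NULL) {
  stopifnot(inherits(t, "planted_tree"))
  fmt <- function(x) sprintf("%.10g", x)
  n_nodes <- 2L * t$n_leaf - 1L
  str <- character(n_nodes)
  for (v in seq_len(n_nodes)) {          # postorder: children ready first
    if (t$is_leaf[v]) {
      str[v] <- t$labels[t$leaf_rank[v]]
    } else {
      str[v] <- paste0("(", str[t$kids[v, 1L]], ",", str[t$kids[v, 2L]], ")")
    }
    str[v] <- paste0(str[v], ":", fmt(t$brlen[v]))
  }
  out <- paste0(str[t$root], ";")
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}

#' @export
print.planted_tree <- function(x, ...) {
  cat("<planted_tree> ", x$n_leaf, " leaves, planted edge length ",
      format(x$brlen[x$root]), "\n", sep = "")
  lab <- x$labels
  if (x$n_leaf > 8L) lab <- c(lab[1:8], "...")
  cat("  leaves (left to right): ", paste(lab, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# integer edge-depth of every node below the planted root (top node = 0)
node_depths <- function(t) {
  n_nodes <- 2L * t$n_leaf - 1L
  d <- integer(n_nodes)
  for (v in rev(seq_len(n_nodes))) {
    if (!is.na(t$parent[v])) d[v] <- d[t$parent[v]] + 1L
  }
  d
}

# weighted length of the path from each node to the planted root o,
# including the node's own parent edge and the planted edge
node_path_lengths <- function(t) {
  n_nodes <- 2L * t$n_leaf - 1L
  pl <- numeric(n_nodes)
  pl[t$root] <- t$brlen[t$root]
  for (v in rev(seq_len(n_nodes))) {
    if (!is.na(t$parent[v])) pl[v] <- pl[t$parent[v]] + t$brlen[v]
  }
  pl
}

#' Leaf depths
#'
#' Edge-depth of every leaf. Two conventions are supported: *planted* depth
#' counts edges on the path to the planted root `o` (so the planted edge is
#' included), *unplanted* depth counts edges to `o`'s child, the convention
#' under which a single-leaf tree has depth 0. The two differ by exactly 1 per
#' leaf.
#'
#' @param t a `planted_tree`.
#' @param planted count the planted edge? Default `FALSE`.
#' @return A tibble with columns `leaf` (left-to-right rank), `label`, `depth`.
#' @examples
#' tr <- read_planted_tree("((A:1,B:1):1,(C:1,D:1):1):1;")
#' leaf_depths(tr, planted = TRUE)
#' @export
leaf_depths <- function(t, planted = FALSE) {
  stopifnot(inherits(t, "planted_tree"))
  d <- node_depths(t)[t$leaf_ids] + as.integer(planted)
  tibble(leaf = seq_len(t$n_leaf), label = t$labels, depth = d)
}

#' External path length
#'
#' The sum of leaf edge-depths, `EPL(T) = sum_i depth(i)`. The ratio
#' `EPL / n^2` controls how strongly the Haar-like basis sparsifies the
#' tree's covariance matrix (see [sparsity_bound()]).
#'
#' @inheritParams leaf_depths
#' @return A single number.
#' @export
external_path_length <- function(t, planted = FALSE) {
  sum(leaf_depths(t, planted = planted)$depth)
}

#' Descendant leaf counts
#'
#' Number of leaves descending from every node (leaves count themselves).
#'
#' @param t a `planted_tree`.
#' @return A tibble with columns `node` (postorder id), `is_leaf`, `n_leaves`.
#' @export
subtree_leaf_counts <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  tibble(node = seq_len(2L * t$n_leaf - 1L), is_leaf = t$is_leaf,
         n_leaves = t$n_desc)
}

#' Median minor split size by clade size
#'
#' For every interior split of a clade of size `m` into subclades of sizes
#' `(i, m - i)`, records the minor size `min(i, m - i)`, then reports the
#' median per clade size `m`. In real-world phylogenies and under the critical
#' beta-splitting model the median minor size grows like `sqrt(m)`; under the
#' uniform (Catalan) model it grows only logarithmically — the balance
#' diagnostic separating the two ensembles.
#'
#' @param t a `planted_tree`.
#' @return A tibble with columns `clade_size`, `n_splits`, `median_minor`,
#'   sorted by decreasing `clade_size`; empty for trees with fewer than two
#'   leaves.
#' @export
minor_split_summary <- function(t) {
  stopifnot(inherits(t, "planted_tree"))
  if (t$n_leaf < 2L)
    return(tibble(clade_size = integer(), n_splits = integer(),
                  median_minor = numeric()))
  internal <- which(!t$is_leaf)
  m <- t$n_desc[internal]
  i <- t$n_desc[t$kids[internal, 1L]]
  tibble(clade_size = m, minor = pmin(i, m - i)) |>
    dplyr::group_by(.data$clade_size) |>
    dplyr::summarise(n_splits = dplyr::n(),
                     median_minor = median(.data$minor), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$clade_size))
}
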