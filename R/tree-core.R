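# Core rooted-tree representation shared by species trees and gene trees.
#
# A tree is a list of parallel per-node vectors indexed 1..n_nodes:
#   parent   integer, NA at the root
#   children list of integer vectors (input order kept; order is not semantic)
#   label    character; unique and non-empty on leaves, internal nodes keep
#            their input name or receive a generated preorder id
#   depth    integer edge distance to the root (depth(root) = 0)
# plus an Euler-tour / sparse-table index answering lca queries in O(1).

new_plr_tree <- function(parent, label, subclass = character()) {
  n <- length(parent)
  if (n == 0L) stop("tree must have at least one node")
  if (length(label) != n) stop("parent and label lengths differ")
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (any(parent[-root] < 1L | parent[-root] > n, na.rm = TRUE))
    stop("parent vector out of range")

  children <- vector("list", n)
  ord <- seq_len(n)[-root]
  for (v in ord) children[[parent[v]]] <- c(children[[parent[v]]], v)
  is_leaf <- lengths(children) == 0L

  # iterative preorder (children left to right) and depth
  preorder <- integer(n)
  depth <- integer(n)
  stack <- integer(n)
  stack[1L] <- root
  top <- 1L
  k <- 0L
  while (top > 0L) {
    v <- stack[top]
    top <- top - 1L
    k <- k + 1L
    preorder[k] <- v
    kids <- children[[v]]
    nk <- length(kids)
    if (nk > 0L) {
      for (i in nk:1L) {
        top <- top + 1L
        stack[top] <- kids[i]
      }
      depth[kids] <- depth[v] + 1L
    }
  }
  if (k != n) stop("parent vector does not describe a single connected tree")
  postorder <- rev(preorder)

  label <- as.character(label)
  need_id <- is.na(label) | label == ""
  if (any(need_id)) {
    rank <- integer(n)
    rank[preorder] <- seq_len(n)
    gen <- paste0("node_", rank[need_id])
    while (any(gen %in% label[!need_id])) gen <- paste0(gen, "_g")
    label[need_id] <- gen
  }
  leaf_lab <- label[is_leaf]
  if (anyDuplicated(leaf_lab)) {
    stop("duplicate leaf names: ",
         paste(unique(leaf_lab[duplicated(leaf_lab)]), collapse = ", "))
  }

  tree <- list(
    n_nodes = n, root = root, parent = parent, children = children,
    label = label, is_leaf = is_leaf, depth = depth,
    preorder = preorder, postorder = postorder
  )
  tree$lca_index <- build_euler_index(tree)
  class(tree) <- c(subclass, "plr_tree")
  tree
}

#' Build a lowest-common-ancestor index for a rooted tree
#'
#' Precomputes an Euler tour of the tree and a sparse table of range-minimum
#' positions over tour depths, so that any lca query is answered in constant
#' time after O(n log n) preprocessing. Trees built by this package carry the
#' index already; this constructor is exposed for completeness and for
#' rebuilding after manual surgery on a tree structure.
#'
#' @param tree a tree as returned by [parse_species_tree()] or
#'   [parse_gene_tree()].
#' @return an lca index (list with the Euler tour, first-occurrence positions
#'   and the sparse table), usable via [tree_lca()].
#' @export
build_lca_index <- function(tree) {
  stopifnot(inherits(tree, "plr_tree"))
  build_euler_index(tree)
}

build_euler_index <- function(tree) {
  n <- tree$n_nodes
  m <- 2L * n - 1L
  euler <- integer(m)
  first <- integer(n)
  stack_node <- integer(m)
  stack_ci <- integer(m)
  top <- 1L
  stack_node[1L] <- tree$root
  stack_ci[1L] <- 0L
  pos <- 0L
  while (top > 0L) {
    v <- stack_node[top]
    ci <- stack_ci[top]
    if (ci == 0L) {
      pos <- pos + 1L
      euler[pos] <- v
      first[v] <- pos
    }
    kids <- tree$children[[v]]
    if (ci < length(kids)) {
      stack_ci[top] <- ci + 1L
      top <- top + 1L
      stack_node[top] <- kids[ci + 1L]
      stack_ci[top] <- 0L
    } else {
      top <- top - 1L
      if (top > 0L) {
        pos <- pos + 1L
        euler[pos] <- stack_node[top]
      }
    }
  }
  ed <- tree$depth[euler]
  kmax <- if (m > 1L) floor(log2(m)) else 0L
  sp <- matrix(0L, nrow = m, ncol = kmax + 1L)
  sp[, 1L] <- seq_len(m)
  if (kmax >= 1L) {
    for (k in seq_len(kmax)) {
      half <- 2L^(k - 1L)
      len <- m - 2L^k + 1L
      i <- seq_len(len)
      a <- sp[i, k]
      b <- sp[i + half, k]
      sp[i, k + 1L] <- ifelse(ed[a] <= ed[b], a, b)
    }
  }
  list(euler = euler, first = first, euler_depth = ed, sparse = sp)
}

# vectorized lca over node-id vectors, via the cached index
lca_nodes <- function(tree, u, v) {
  idx <- tree$lca_index
  l <- pmin(idx$first[u], idx$first[v])
  r <- pmax(idx$first[u], idx$first[v])
  len <- r - l + 1L
  k <- floor(log2(len))
  half <- as.integer(2L^k)
  a <- idx$sparse[cbind(l, k + 1L)]
  b <- idx$sparse[cbind(r - half + 1L, k + 1L)]
  pick <- ifelse(idx$euler_depth[a] <= idx$euler_depth[b], a, b)
  idx$euler[pick]
}

resolve_nodes <- function(tree, x) {
  if (is.character(x)) {
    out <- match(x, tree$label)
    if (anyNA(out)) stop("unknown node label(s): ",
                         paste(x[is.na(out)], collapse = ", "))
    return(out)
  }
  x <- as.integer(x)
  if (any(x < 1L | x > tree$n_nodes)) stop("node id out of range")
  x
}

#' Lowest common ancestor of two nodes
#'
#' @param tree a tree of this package.
#' @param u,v node ids (integers) or node labels (character); recycled to a
#'   common length, so vectors of pairs are answered in one call.
#' @return integer node id(s) of the lca.
#' @export
tree_lca <- function(tree, u, v) {
  stopifnot(inherits(tree, "plr_tree"))
  lca_nodes(tree, resolve_nodes(tree, u), resolve_nodes(tree, v))
}

#' Path length between two nodes of the same tree
#'
#' Distances are edge counts (unit branch lengths), computed as
#' `depth(u) + depth(v) - 2 * depth(lca(u, v))`.
#'
#' @inheritParams tree_lca
#' @return non-negative integer distance(s).
#' @export
tree_dist <- function(tree, u, v) {
  stopifnot(inherits(tree, "plr_tree"))
  u <- resolve_nodes(tree, u)
  v <- resolve_nodes(tree, v)
  a <- lca_nodes(tree, u, v)
  tree$depth[u] + tree$depth[v] - 2L * tree$depth[a]
}

#' Depth of a node (edge distance to the root; root has depth 0)
#' @inheritParams tree_lca
#' @param v node id(s) or label(s).
#' @return integer depth(s).
#' @export
tree_depth <- function(tree, v) {
  stopifnot(inherits(tree, "plr_tree"))
  tree$depth[resolve_nodes(tree, v)]
}

n_leaves <- function(tree) sum(tree$is_leaf)

leaf_labels <- function(tree) tree$label[tree$is_leaf]

# TRUE iff u is a descendant of v (or u == v)
is_descendant <- function(tree, u, v) {
  lca_nodes(tree, u, v) == v
}

# leaf-label clade below each node, as a sorted comma-joined key
clade_keys <- function(tree) {
  keys <- character(tree$n_nodes)
  for (v in tree$postorder) {
    if (tree$is_leaf[v]) {
      keys[v] <- tree$label[v]
    } else {
      parts <- keys[tree$children[[v]]]
      keys[v] <- paste(sort(unlist(strsplit(parts, ",", fixed = TRUE))),
                       collapse = ",")
    }
  }
  keys
}

# leaf-labelled topology key, invariant under child order and internal names
topology_key <- function(tree) {
  keys <- character(tree$n_nodes)
  for (v in tree$postorder) {
    if (tree$is_leaf[v]) {
      keys[v] <- tree$label[v]
    } else {
      keys[v] <- paste0("(", paste(sort(keys[tree$children[[v]]]),
                                   collapse = ","), ")")
    }
  }
  keys[tree$root]
}

#' @export
print.plr_tree <- function(x, ...) {
  kind <- if (inherits(x, "species_tree")) "species tree" else "gene tree"
  cat(sprintf("<%s: %d leaves, %d nodes>\n", kind, n_leaves(x), x$n_nodes))
  cat(" leaves:", paste(utils::head(leaf_labels(x), 10L), collapse = ", "))
  if (n_leaves(x) > 10L) cat(", ...")
  cat("\n")
  invisible(x)
}
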