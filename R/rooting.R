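# Rooting-hypothesis evaluation: enumerate every rooting of an unrooted
# gene tree, lca-reconcile each with the species tree, and rank them by PLR
# distance to a reference reconciliation, reporting the full Best set.
# Unrooted trees are carried in the usual rooted representation with a
# multifurcating (>= 3 children) center node.

#' Enumerate all rootings of an unrooted gene tree
#'
#' For every edge of the unrooted tree, subdivides the edge with a new node
#' and roots the tree there, so a tree with `m` edges yields `m` rooted
#' candidates, each with a binary root and the same leaf set. The input must
#' have no degree-2 node (its representation root needs at least three
#' children).
#'
#' @param tree an unrooted tree parsed with [parse_gene_tree()] from Newick
#'   with a multifurcating outermost grouping, e.g. `"(a,b,(c,d));"`.
#' @return list of rooted `gene_tree`s; each carries attribute `edge`
#'   naming the subdivided edge as `"<child>--<parent>"` labels.
#' @export
enumerate_rootings <- function(tree) {
  stopifnot(inherits(tree, "plr_tree"))
  deg <- lengths(tree$children) + ifelse(is.na(tree$parent), 0L, 1L)
  if (any(deg == 2L))
    stop("unrooted tree must not contain degree-2 nodes; node '",
         tree$label[which(deg == 2L)[1L]], "' has degree 2")
  n <- tree$n_nodes
  edges <- cbind(child = setdiff(seq_len(n), tree$root))
  out <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    v <- edges[e, "child"]
    u <- tree$parent[v]
    out[[e]] <- reroot_on_edge(tree, u, v)
    attr(out[[e]], "edge") <- paste0(tree$label[v], "--", tree$label[u])
  }
  out
}

# root the (unrooted) tree on the edge u-v by subdividing it with a new root
reroot_on_edge <- function(tree, u, v) {
  n <- tree$n_nodes
  root_id <- n + 1L
  parent <- integer(root_id)
  parent[root_id] <- NA_integer_
  parent[u] <- root_id
  parent[v] <- root_id
  # orient every other node away from the new root along the undirected tree
  neighbors <- function(w) {
    out <- tree$children[[w]]
    if (!is.na(tree$parent[w])) out <- c(out, tree$parent[w])
    out
  }
  assign_below <- function(start, avoid) {
    stack <- start
    from <- avoid
    # iterative DFS carrying the predecessor of each stacked node
    while (length(stack)) {
      w <- stack[[length(stack)]]
      f <- from[[length(from)]]
      stack <- stack[-length(stack)]
      from <- from[-length(from)]
      for (x in neighbors(w)) {
        if (x == f) next
        parent[x] <<- w
        stack <- c(stack, x)
        from <- c(from, w)
      }
    }
  }
  assign_below(u, v)
  assign_below(v, u)
  gene_tree_from_parent(parent, c(tree$label, ""))
}

#' Suppress the root of a binary rooted gene tree
#'
#' Merges the two root children into one multifurcating representation node,
#' yielding the unrooted version of the tree — the input from which
#' [enumerate_rootings()] regenerates all rooting hypotheses.
#'
#' @param tree a rooted `gene_tree` whose root has two children, at least
#'   one internal.
#' @return the unrooted tree (representation root with >= 3 children).
#' @export
unroot_gene_tree <- function(tree) {
  stopifnot(inherits(tree, "plr_tree"))
  kids <- tree$children[[tree$root]]
  if (length(kids) != 2L)
    stop("root must have exactly two children")
  keep_int <- kids[!tree$is_leaf[kids]]
  if (length(keep_int) == 0L)
    stop("cannot unroot a two-leaf tree")
  center <- keep_int[1L]
  other <- setdiff(kids, center)
  keep <- setdiff(seq_len(tree$n_nodes), tree$root)
  new_id <- integer(tree$n_nodes)
  new_id[keep] <- seq_along(keep)
  parent <- tree$parent[keep]
  parent[new_id[center]] <- NA_integer_
  parent[new_id[other]] <- center
  parent[!is.na(parent)] <- new_id[parent[!is.na(parent)]]
  gene_tree_from_parent(parent, tree$label[keep])
}

#' Reconcile one rooting candidate with the species tree
#'
#' Applies the traditional lca-mapping and the lca event rule to a rooted
#' gene tree; the result always satisfies the reconciliation requirements.
#'
#' @param tree a rooted `gene_tree`.
#' @param species the `species_tree`.
#' @param leaf_species named character vector, gene leaf -> species leaf.
#' @return a `reconciled_gene_tree`.
#' @export
reconcile_rooting <- function(tree, species, leaf_species) {
  lca_reconcile(tree, species, leaf_species)
}

#' Score all rootings of an unrooted gene tree against a reference
#'
#' Every rooting candidate is lca-reconciled with the species tree and
#' scored by its PLR dissimilarity to the reference reconciliation. Ties are
#' never broken: the full set of minimizers (the Best set) is reported, and
#' its size is itself a measurement of how sharply the dissimilarity
#' discriminates rootings.
#'
#' @param tree the unrooted gene tree (see [enumerate_rootings()]).
#' @param reference the reference `reconciled_gene_tree`; must share the
#'   leaf set and species tree with the candidates.
#' @param alpha weight in `[0,1]` or `"1/n"`.
#' @param leaf_species optional gene-leaf -> species map; defaults to the
#'   reference's own leaf species.
#' @return a `rooting_report`: data frame `candidates` (edge id, directed
#'   components, `d_plr`, `in_best`), the reconciled candidates, `best`
#'   (indices), `best_size` and `unique_best`.
#' @export
best_rootings <- function(tree, reference, alpha = 0.5, leaf_species = NULL) {
  stopifnot(inherits(reference, "reconciled_gene_tree"))
  if (is.null(leaf_species)) leaf_species <- reconciled_leaf_species(reference)
  if (!setequal(leaf_labels(tree), leaf_labels(reference$gene_tree)))
    stop("candidate rootings incomparable with the reference: leaf sets differ")
  rootings <- enumerate_rootings(tree)
  recs <- vector("list", length(rootings))
  rows <- vector("list", length(rootings))
  for (i in seq_along(rootings)) {
    recs[[i]] <- reconcile_rooting(rootings[[i]], reference$species,
                                   leaf_species)
    d <- d_plr(recs[[i]], reference, alpha)
    if (!d$comparable)
      stop("candidate rooting incomparable with the reference: ",
           paste(d$violations, collapse = "; "))
    rows[[i]] <- data.frame(
      edge = attr(rootings[[i]], "edge"),
      d_path_12 = d$d_path_12, d_lbl_12 = d$d_lbl_12,
      d_path_21 = d$d_path_21, d_lbl_21 = d$d_lbl_21,
      d_plr = d$d_plr, stringsAsFactors = FALSE)
  }
  candidates <- do.call(rbind, rows)
  best_val <- min(candidates$d_plr)
  best <- which(candidates$d_plr == best_val)
  candidates$in_best <- candidates$d_plr == best_val
  structure(
    list(candidates = candidates, reconciliations = recs, best = best,
         best_value = best_val, best_size = length(best),
         unique_best = length(best) == 1L),
    class = "rooting_report")
}

#' @export
print.rooting_report <- function(x, ...) {
  cat(sprintf("<rooting report: %d candidates, best d_plr = %g, best set size %d%s>\n",
              nrow(x$candidates), x$best_value, x$best_size,
              if (x$unique_best) " (unique)" else ""))
  print(utils::head(x$candidates[order(x$candidates$d_plr), ], 10L))
  invisible(x)
}
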