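# Least duplication-resolved (LDR) normal forms. An edge uv of a reconciled
# gene tree is redundant when both endpoints are duplications in the same
# species; contracting all redundant edges collapses duplication chains into
# polytomies and gives the unique LDR form LR(G). Two reconciliations are
# LDR-equivalent when their LDR forms are isomorphic.

#' Redundant edges of a reconciled gene tree
#'
#' An edge parent-child is redundant if both endpoints are duplications
#' mapped to the same species — a topological split inside a duplication
#' chain that carries no phylogenetic signal. The tree is least
#' duplication-resolved iff this set is empty.
#'
#' @param r a `reconciled_gene_tree`.
#' @return data frame with columns `parent`, `child` (node ids),
#'   `parent_label`, `child_label`, `species`.
#' @export
redundant_edges <- function(r) {
  stopifnot(inherits(r, "reconciled_gene_tree"))
  g <- r$gene_tree
  child <- setdiff(seq_len(g$n_nodes), g$root)
  pa <- g$parent[child]
  red <- r$event[child] == "dup" & r$event[pa] == "dup" &
    r$mu[child] == r$mu[pa]
  child <- child[red]
  pa <- pa[red]
  data.frame(parent = pa, child = child,
             parent_label = g$label[pa], child_label = g$label[child],
             species = r$species$label[r$mu[child]],
             stringsAsFactors = FALSE)
}

# rebuild a reconciliation with one node removed, its children re-attached
# to its parent; the parent subsumes the child
drop_gene_node <- function(r, v) {
  g <- r$gene_tree
  keep <- setdiff(seq_len(g$n_nodes), v)
  new_id <- integer(g$n_nodes)
  new_id[keep] <- seq_along(keep)
  parent <- g$parent[keep]
  reroute <- !is.na(parent) & parent == v
  parent[reroute] <- g$parent[v]
  parent[!is.na(parent)] <- new_id[parent[!is.na(parent)]]
  tree <- gene_tree_from_parent(parent, g$label[keep])
  new_reconciled(tree, r$species, r$mu[keep], r$event[keep])
}

#' Contract one redundant edge
#'
#' Removes the child endpoint and re-attaches its children to the parent,
#' which keeps its identity, species and label ("the parent subsumes the
#' child"). Errors if the edge is not redundant.
#'
#' @param r a `reconciled_gene_tree`.
#' @param parent,child node ids or labels of the edge endpoints.
#' @return the contracted `reconciled_gene_tree`.
#' @export
contract_edge <- function(r, parent, child) {
  g <- r$gene_tree
  parent <- resolve_nodes(g, parent)
  child <- resolve_nodes(g, child)
  if (is.na(g$parent[child]) || g$parent[child] != parent)
    stop("not an edge of the gene tree")
  if (!(r$event[parent] == "dup" && r$event[child] == "dup" &&
        r$mu[parent] == r$mu[child]))
    stop("edge is not redundant (needs dup-dup in the same species)")
  drop_gene_node(r, child)
}

#' Least duplication-resolved form LR(G)
#'
#' Contracts redundant edges until none remain. The result is unique — the
#' order of contractions does not matter — and is a fixpoint: applying LR
#' again changes nothing.
#'
#' @param r a `reconciled_gene_tree`.
#' @return the LDR `reconciled_gene_tree`.
#' @export
least_duplication_resolved <- function(r) {
  repeat {
    red <- redundant_edges(r)
    if (nrow(red) == 0L) return(r)
    r <- contract_edge(r, red$parent[1L], red$child[1L])
  }
}

# canonical per-node keys; two reconciliations are isomorphic iff the root
# keys agree (leaves are uniquely named, so clades force the bijection)
reconciliation_canon <- function(r) {
  g <- r$gene_tree
  sp_key <- clade_keys(r$species)
  keys <- character(g$n_nodes)
  for (v in g$postorder) {
    if (g$is_leaf[v]) {
      keys[v] <- paste0("L[", g$label[v], "|", sp_key[r$mu[v]], "]")
    } else {
      keys[v] <- paste0(r$event[v], "@", sp_key[r$mu[v]],
                        "(", paste(sort(keys[g$children[[v]]]),
                                   collapse = ","), ")")
    }
  }
  keys[g$root]
}

#' Isomorphism of reconciled gene trees
#'
#' Two reconciled gene trees are isomorphic when a bijection fixing the
#' (shared, uniquely named) leaves preserves edges, species maps and event
#' labels. Because the leaves pin down every clade, the bijection is forced,
#' and the test reduces to comparing canonical bottom-up clade encodings.
#'
#' @param r1,r2 `reconciled_gene_tree` objects.
#' @return logical.
#' @export
is_isomorphic <- function(r1, r2) {
  stopifnot(inherits(r1, "reconciled_gene_tree"),
            inherits(r2, "reconciled_gene_tree"))
  if (species_tree_key(r1$species) != species_tree_key(r2$species))
    return(FALSE)
  identical(reconciliation_canon(r1), reconciliation_canon(r2))
}

#' LDR-equivalence of reconciled gene trees
#'
#' TRUE iff the least duplication-resolved forms are isomorphic — every
#' disagreement between the two trees lies inside same-species duplication
#' chains. This is the equality notion under which the PLR dissimilarity is
#' a semi-metric for any weight strictly between 0 and 1.
#'
#' @inheritParams is_isomorphic
#' @return logical.
#' @export
is_ldr_equivalent <- function(r1, r2) {
  is_isomorphic(least_duplication_resolved(r1),
                least_duplication_resolved(r2))
}
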