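# Species trees: rooted, strictly binary, uniquely named extant species.

#' Parse a rooted binary species tree from Newick
#'
#' Species trees are assumed binary throughout: every internal node must have
#' exactly two children, and non-binary input is rejected rather than
#' resolved. Leaf names are the species identifiers and must be unique and
#' non-empty. Branch lengths, if present, are discarded (all distances are
#' edge counts).
#'
#' @param text a rooted Newick string, e.g. `"((C,D)z1,(A,B)z2)z0;"`.
#' @return a `species_tree` object carrying node depths and an lca index.
#' @examples
#' s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
#' tree_dist(s, "z1", "z0")
#' @export
parse_species_tree <- function(text) {
  p <- parse_newick(text)
  tree <- new_plr_tree(p$parent, p$label, subclass = "species_tree")
  check_species_tree(tree)
  tree
}

check_species_tree <- function(tree) {
  deg <- lengths(tree$children)
  bad <- which(deg != 0L & deg != 2L)
  if (length(bad))
    stop("species tree must be binary; node '", tree$label[bad[1L]],
         "' has ", deg[bad[1L]], " child(ren)")
  if (any(tree$is_leaf & !nzchar(tree$label)))
    stop("species tree leaves must be named")
  invisible(tree)
}

species_tree_from_parent <- function(parent, label) {
  tree <- new_plr_tree(parent, label, subclass = "species_tree")
  check_species_tree(tree)
  tree
}

#' Parse a gene tree from Newick
#'
#' Gene trees are rooted and may contain polytomies (every internal node has
#' at least two children). Leaf names are the gene identifiers.
#'
#' @param text a rooted Newick string.
#' @return a `gene_tree` object.
#' @export
parse_gene_tree <- function(text) {
  p <- parse_newick(text)
  tree <- new_plr_tree(p$parent, p$label, subclass = "gene_tree")
  check_gene_tree(tree)
  tree
}

check_gene_tree <- function(tree) {
  deg <- lengths(tree$children)
  bad <- which(deg == 1L)
  if (length(bad))
    stop("gene tree internal nodes need at least two children; node '",
         tree$label[bad[1L]], "' has one")
  if (any(tree$is_leaf & !nzchar(tree$label)))
    stop("gene tree leaves must be named")
  invisible(tree)
}

gene_tree_from_parent <- function(parent, label) {
  tree <- new_plr_tree(parent, label, subclass = "gene_tree")
  check_gene_tree(tree)
  tree
}

# key identifying the leaf-labelled species tree topology, used to decide
# whether two reconciliations refer to the same species tree
species_tree_key <- function(s) topology_key(s)

#' A caterpillar species tree on n leaves
#'
#' The caterpillar maximizes the root-to-internal-node distance sum `H(S)`
#' at fixed leaf count and hence the PLR diameter; exposed for diameter
#' experiments.
#'
#' @param n number of species, at least 2.
#' @param labels optional leaf names (default `s1..sn`).
#' @return a `species_tree`.
#' @export
caterpillar_species_tree <- function(n, labels = paste0("s", seq_len(n))) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 species")
  stopifnot(length(labels) == n)
  # internal spine 1..n-1 (1 = root), leaves hang off the spine
  parent <- integer(2L * n - 1L)
  lab <- character(2L * n - 1L)
  parent[1L] <- NA_integer_
  if (n > 2L) for (i in 2L:(n - 1L)) parent[i] <- i - 1L
  for (i in seq_len(n - 1L)) {
    parent[n - 1L + i] <- i       # one leaf per spine node
    lab[n - 1L + i] <- labels[i]
  }
  parent[2L * n - 1L] <- n - 1L   # deepest spine node has two leaves
  lab[2L * n - 1L] <- labels[n]
  species_tree_from_parent(parent, lab)
}
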