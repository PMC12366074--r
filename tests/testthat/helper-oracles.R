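# Brute-force oracles, independent of the package's indexed implementations:
# everything here walks parent links or enumerates leaves explicitly.

ancestors_of <- function(tree, v) {
  out <- v
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    out <- c(out, v)
  }
  out
}

naive_lca <- function(tree, u, v) {
  au <- ancestors_of(tree, u)
  av <- ancestors_of(tree, v)
  common <- intersect(au, av)
  common[1L] # ancestors_of lists bottom-up, so the first common is lowest
}

naive_dist <- function(tree, u, v) {
  a <- naive_lca(tree, u, v)
  au <- ancestors_of(tree, u)
  av <- ancestors_of(tree, v)
  (which(au == a) - 1L) + (which(av == a) - 1L)
}

naive_clade <- function(tree, v) {
  if (tree$is_leaf[v]) return(tree$label[v])
  sort(unlist(lapply(tree$children[[v]], naive_clade, tree = tree)))
}

# lowest node of the target tree whose clade covers the source node's clade
naive_m_map <- function(r1, r2) {
  g1 <- r1$gene_tree
  g2 <- r2$gene_tree
  clades2 <- lapply(seq_len(g2$n_nodes), naive_clade, tree = g2)
  vapply(seq_len(g1$n_nodes), function(v) {
    cl <- naive_clade(g1, v)
    covering <- which(vapply(clades2, function(x) all(cl %in% x), TRUE))
    covering[which.max(g2$depth[covering])]
  }, 1L)
}

naive_lca_map <- function(gene_tree, species, leaf_species) {
  vapply(seq_len(gene_tree$n_nodes), function(v) {
    sp <- match(leaf_species[naive_clade(gene_tree, v)], species$label)
    Reduce(function(a, b) naive_lca(species, a, b), sp)
  }, 1L)
}

# canonical set of leaf bipartitions of an unrooted tree (any rooted
# representation of the same unrooted topology gives the same set)
unrooted_splits <- function(tree) {
  leaves <- sort(leaf_labels(tree))
  keys <- vapply(setdiff(seq_len(tree$n_nodes), tree$root), function(v) {
    cl <- naive_clade(tree, v)
    comp <- setdiff(leaves, cl)
    a <- paste(cl, collapse = ",")
    b <- paste(comp, collapse = ",")
    if (a < b) paste(a, b, sep = " | ") else paste(b, a, sep = " | ")
  }, "")
  sort(unique(keys))
}

# one simulated reconciliation over a fresh random scenario
sim_one <- function(n_species = 8, max_per_species = 2, seed = NULL,
                    species = NULL, gene_set = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(species)) species <- random_species_tree(n_species)
  if (is.null(gene_set)) gene_set <- random_gene_set(species, max_per_species)
  cfg <- simulation_config(species, gene_set$genes,
                          gene_set$species_assignment, ...)
  simulate_reconciliation(cfg)
}

# a comparable pair: two independent scenarios over the same gene set
sim_pair <- function(n_species = 8, max_per_species = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- random_species_tree(n_species)
  gs <- random_gene_set(species, max_per_species)
  list(r1 = sim_one(species = species, gene_set = gs),
       r2 = sim_one(species = species, gene_set = gs),
       species = species)
}
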