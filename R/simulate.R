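# Bottom-up simulation of random reconciliation scenarios on a fixed leaf
# set, a simple random species-tree and gene-set generator, and
# deterministic constructors for the worked-example fixtures.

#' Random binary species tree
#'
#' Uniform sequential leaf attachment: starting from the two-leaf tree, each
#' new leaf is attached on the edge above a uniformly chosen existing node
#' (choosing the root grows a new root). A lightweight stand-in for
#' dedicated species-tree samplers; only shape diversity matters for the
#' distance experiments here.
#'
#' @param n number of species, at least 2.
#' @param seed optional integer seed for reproducibility.
#' @param labels optional leaf names (default `s1..sn`).
#' @return a `species_tree`.
#' @export
random_species_tree <- function(n, seed = NULL,
                                labels = paste0("s", seq_len(n))) {
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  parent <- c(NA_integer_, 1L, 1L)
  is_leaf <- c(FALSE, TRUE, TRUE)
  while (sum(is_leaf) < n) {
    v <- sample.int(length(parent), 1L)
    new_int <- length(parent) + 1L
    new_leaf <- length(parent) + 2L
    if (is.na(parent[v])) {
      parent[new_int] <- NA_integer_
      parent[v] <- new_int
    } else {
      parent[new_int] <- parent[v]
      parent[v] <- new_int
    }
    parent[new_leaf] <- new_int
    is_leaf[new_int] <- FALSE
    is_leaf[new_leaf] <- TRUE
  }
  lab <- character(length(parent))
  lab[is_leaf] <- labels[seq_len(n)]
  species_tree_from_parent(parent, lab)
}

#' Random gene set over a species tree
#'
#' Draws, for each species, a gene count uniformly from `1..max_per_species`
#' (so every species keeps at least one gene) and names the genes
#' `<species>_<index>`, making the species assignment recoverable from the
#' names. `max_per_species = 1` gives the one-gene-per-species regime used
#' by the diameter theory.
#'
#' @param s a `species_tree`.
#' @param max_per_species upper bound on genes per species, at least 1.
#' @param seed optional integer seed.
#' @return list with `genes` (character) and `species_assignment` (named
#'   character, gene -> species leaf).
#' @export
random_gene_set <- function(s, max_per_species = 1L, seed = NULL) {
  stopifnot(inherits(s, "species_tree"))
  j <- as.integer(max_per_species)
  if (j < 1L) stop("max_per_species must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sp <- leaf_labels(s)
  counts <- if (j == 1L) rep(1L, length(sp)) else
    sample.int(j, length(sp), replace = TRUE)
  genes <- unlist(lapply(seq_along(sp), function(i)
    paste0(sp[i], "_", seq_len(counts[i]))))
  sigma <- stats::setNames(rep(sp, counts), genes)
  list(genes = genes, species_assignment = sigma)
}

#' Configuration of the reconciliation simulator
#'
#' @param species_tree the fixed `species_tree`.
#' @param genes character vector of gene identifiers (the fixed leaf set).
#' @param species_assignment named character vector, gene -> species leaf.
#' @param decay_rate positive exponential decay rate of the pair-selection
#'   kernel `exp(-decay_rate * d)` over species distance `d` (default 0.7).
#' @param spec_probability probability of choosing a speciation when the
#'   lca rule permits one (default 0.5).
#' @param seed optional integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(species_tree, genes, species_assignment,
                              decay_rate = 0.7, spec_probability = 0.5,
                              seed = NULL) {
  stopifnot(inherits(species_tree, "species_tree"))
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene set must be non-empty")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (!all(genes %in% names(species_assignment)))
    stop("every gene needs a species assignment")
  sp <- species_assignment[genes]
  if (!all(sp %in% leaf_labels(species_tree)))
    stop("species assignment refers to unknown species leaf(s)")
  if (!(is.numeric(decay_rate) && decay_rate > 0))
    stop("decay_rate must be positive")
  if (!(is.numeric(spec_probability) && spec_probability >= 0 &&
        spec_probability <= 1))
    stop("spec_probability must lie in [0,1]")
  structure(
    list(species_tree = species_tree, genes = genes,
         species_assignment = sp, decay_rate = decay_rate,
         spec_probability = spec_probability, seed = seed),
    class = "simulation_config")
}

#' Simulate one random reconciliation scenario
#'
#' Builds a reconciled gene tree bottom-up over the fixed gene set: at each
#' iteration an unordered pair of active lineages is drawn with probability
#' proportional to `exp(-decay_rate * d)`, `d` the species-tree distance
#' between their current species, and replaced by a new parent. The parent's
#' species is the lca of the pair's species (so the output uses the
#' lca-mapping throughout); its label is forced to duplication whenever its
#' species coincides with a child's, and otherwise drawn as speciation with
#' `spec_probability`. The decay keeps close gene lineages from merging
#' across distant species, which would drive every ancestral node to the
#' species root as a duplication. The output is binary with one internal
#' node per merge and always satisfies the reconciliation requirements.
#'
#' @param config a [simulation_config()].
#' @return a valid `reconciled_gene_tree`.
#' @export
simulate_reconciliation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  s <- config$species_tree
  genes <- config$genes
  m <- length(genes)
  sp_leaf <- match(config$species_assignment, s$label)

  n_total <- 2L * m - 1L
  parent <- rep(NA_integer_, n_total)
  label <- character(n_total)
  label[seq_len(m)] <- genes
  mu <- integer(n_total)
  mu[seq_len(m)] <- sp_leaf
  event <- rep("extant", n_total)

  active <- seq_len(m)
  nxt <- m
  while (length(active) > 1L) {
    k <- length(active)
    pairs <- utils::combn(k, 2L)
    d <- tree_dist(s, mu[active[pairs[1L, ]]], mu[active[pairs[2L, ]]])
    w <- exp(-config$decay_rate * d)
    pick <- sample.int(ncol(pairs), 1L, prob = w)
    i <- active[pairs[1L, pick]]
    j <- active[pairs[2L, pick]]
    nxt <- nxt + 1L
    parent[i] <- nxt
    parent[j] <- nxt
    mu[nxt] <- lca_nodes(s, mu[i], mu[j])
    event[nxt] <- if (mu[nxt] %in% c(mu[i], mu[j])) "dup" else
      if (stats::runif(1L) < config$spec_probability) "spec" else "dup"
    active <- c(setdiff(active, c(i, j)), nxt)
  }
  tree <- gene_tree_from_parent(parent, label)
  new_reconciled(tree, s, mu, event)
}

#' Worked-example fixture: two reconciled trees over four species
#'
#' The four-species tree `((C,D)z1,(A,B)z2)z0` with two reconciled gene
#' trees over genes a, b, c, d that share leaves but differ in topology and
#' labeling; both use the lca-mapping. At `alpha = 0.5` their components are
#' `d_path` 1/0, `d_lbl` 2/2, `d_asym` 1.5/1 and `d_plr` 2.5.
#'
#' @return list with `g1`, `g2` (`reconciled_gene_tree`s) and `species`.
#' @export
fig1_fixture <- function() {
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  g1 <- parse_reconciled_tree(paste0(
    "((c[&&NHX:S=C],d[&&NHX:S=D])x1[&&NHX:S=z1:Ev=dup],",
    "(a[&&NHX:S=A],b[&&NHX:S=B])x2[&&NHX:S=z2:Ev=spec])",
    "x0[&&NHX:S=z0:Ev=spec];"), s)
  g2 <- parse_reconciled_tree(paste0(
    "(d[&&NHX:S=D],(c[&&NHX:S=C],",
    "(a[&&NHX:S=A],b[&&NHX:S=B])y2[&&NHX:S=z2:Ev=dup])",
    "y1[&&NHX:S=z0:Ev=spec])y0[&&NHX:S=z0:Ev=dup];"), s)
  list(g1 = g1, g2 = g2, species = s)
}

#' LDR-equivalence fixture: distance zero across duplication chains
#'
#' Two reconciled gene trees over species `(A,B)X` that disagree only inside
#' same-species duplication chains (in A, in B, and in X above three shared
#' speciation clades). Their PLR dissimilarity is 0 for every alpha, and
#' their least duplication-resolved forms are isomorphic.
#'
#' @return list with `g1`, `g2` and `species`.
#' @export
fig2_fixture <- function() {
  s <- parse_species_tree("(A,B)X;")
  leafs <- function(g) paste0(g, "[&&NHX:S=", toupper(substr(g, 1L, 1L)), "]")
  node <- function(children, lab, sp, ev) {
    paste0("(", paste(children, collapse = ","), ")", lab,
           "[&&NHX:S=", sp, ":Ev=", ev, "]")
  }
  # G1: dup chains shaped ((x1,x2),x3) in A and B, spec clades s1..s3, and a
  # dup chain ((s1,s2),s3) in X
  a_chain1 <- node(c(node(leafs(c("a1", "a2")), "da1", "A", "dup"),
                     leafs("a3")), "da2", "A", "dup")
  b_chain1 <- node(c(node(leafs(c("b1", "b2")), "db1", "B", "dup"),
                     leafs("b3")), "db2", "B", "dup")
  s1 <- node(c(a_chain1, b_chain1), "s1", "X", "spec")
  s2 <- node(leafs(c("a4", "b4")), "s2", "X", "spec")
  s3 <- node(leafs(c("a5", "b5")), "s3", "X", "spec")
  g1 <- parse_reconciled_tree(
    paste0(node(c(node(c(s1, s2), "dx1", "X", "dup"), s3),
                "dx2", "X", "dup"), ";"), s)
  # G2: same spec clades, the chains reshaped to (x1,(x2,x3)) / ((x1,x3),x2)
  a_chain2 <- node(c(leafs("a1"), node(leafs(c("a2", "a3")), "ea1", "A", "dup")),
                   "ea2", "A", "dup")
  b_chain2 <- node(c(node(leafs(c("b1", "b3")), "eb1", "B", "dup"),
                     leafs("b2")), "eb2", "B", "dup")
  t1 <- node(c(a_chain2, b_chain2), "t1", "X", "spec")
  t2 <- node(leafs(c("a4", "b4")), "t2", "X", "spec")
  t3 <- node(leafs(c("a5", "b5")), "t3", "X", "spec")
  g2 <- parse_reconciled_tree(
    paste0(node(c(t1, node(c(t2, t3), "ex1", "X", "dup")),
                "ex2", "X", "dup"), ";"), s)
  list(g1 = g1, g2 = g2, species = s)
}

#' Triangle-inequality violation fixture
#'
#' Three reconciled gene trees over species `((A,B)X,C)Y` built from `k >= 2`
#' duplicated `((a,b),(a,b))` blocks. For every `alpha` in `[0,1]`, the
#' directed components evaluate to `d_asym(G1,G2) = 1 - alpha`,
#' `d_asym(G2,G1) = 1`, `d_asym(G2,G3) = 1 - alpha`,
#' `d_asym(G3,G2) = 1 + alpha`, `d_asym(G1,G3) = (k+1)(1-alpha)` and
#' `d_asym(G3,G1) = 2 + 3 alpha`, so
#' `d_plr(G1,G3) = k(1-alpha) + 2 alpha + 3` exceeds
#' `d_plr(G1,G2) + d_plr(G2,G3) = 4 - alpha`: the PLR dissimilarity is a
#' semi-metric, not a metric, on non-binary trees.
#'
#' @param k number of duplicated blocks, at least 2.
#' @return list with `g1`, `g2`, `g3` and `species`.
#' @export
fig3_fixture <- function(k = 2L) {
  k <- as.integer(k)
  if (k < 2L) stop("the construction needs k >= 2")
  s <- parse_species_tree("((A,B)X,C)Y;")
  aL <- function(i) paste0("a", i, "[&&NHX:S=A]")
  bL <- function(i) paste0("b", i, "[&&NHX:S=B]")
  cL <- "c[&&NHX:S=C]"
  cherry <- function(i, ev) paste0("(", aL(i), ",", bL(i), ")p", i,
                                   "[&&NHX:S=X:Ev=", ev, "]")
  # G1: root dup at Y over k blocks ((a,b),(a,b)) dup at X, plus leaf c
  blocks <- vapply(seq_len(k), function(i) {
    paste0("(", cherry(2L * i - 1L, "spec"), ",", cherry(2L * i, "spec"),
           ")d", i, "[&&NHX:S=X:Ev=dup]")
  }, "")
  g1 <- parse_reconciled_tree(paste0(
    "(", paste(blocks, collapse = ","), ",", cL,
    ")r1[&&NHX:S=Y:Ev=dup];"), s)
  # G2: spec at Y over (2k cherries under one X duplication) and c
  g2 <- parse_reconciled_tree(paste0(
    "((", paste(vapply(seq_len(2L * k), function(i) cherry(i, "spec"), ""),
                collapse = ","),
    ")dx[&&NHX:S=X:Ev=dup],", cL, ")r2[&&NHX:S=Y:Ev=spec];"), s)
  # G3: spec at Y over (spec at X over all-a and all-b dup polytomies) and c
  g3 <- parse_reconciled_tree(paste0(
    "(((", paste(vapply(seq_len(2L * k), aL, ""), collapse = ","),
    ")da[&&NHX:S=A:Ev=dup],(",
    paste(vapply(seq_len(2L * k), bL, ""), collapse = ","),
    ")db[&&NHX:S=B:Ev=dup])sx[&&NHX:S=X:Ev=spec],", cL,
    ")r3[&&NHX:S=Y:Ev=spec];"), s)
  list(g1 = g1, g2 = g2, g3 = g3, species = s)
}

#' Labeled-tree pair for the ELRF diameter bound
#'
#' Two unrooted five-leaf labeled trees with two internal edges each and
#' complementary speciation/duplication patterns; transforming one into the
#' other under label-respecting contractions, extensions and flips takes
#' `7 = 3n - 8` operations, matching [elrf_diameter_bound()]. The trees are
#' returned as rooted representations with a trifurcating center plus their
#' internal label maps; the distance itself is not computed by this package.
#'
#' @return list with `tree1`, `tree2` (each a list `tree`, `labels`),
#'   `n_leaves` and `elrf_bound`.
#' @export
fig4_fixture <- function() {
  t1 <- parse_gene_tree("((l1,l2)u1,l3,(l4,l5)u3)u2;")
  t2 <- parse_gene_tree("((l1,l2)v1,l3,(l4,l5)v3)v2;")
  list(
    tree1 = list(tree = t1,
                 labels = c(u1 = "spec", u2 = "dup", u3 = "spec")),
    tree2 = list(tree = t2,
                 labels = c(v1 = "dup", v2 = "spec", v3 = "dup")),
    n_leaves = 5L, elrf_bound = elrf_diameter_bound(5L))
}
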