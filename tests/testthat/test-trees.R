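# Tree data model: parsing, validity rules, lca/depth/distance services.

test_that("species tree parsing enforces the binary, uniquely-leaved model", {
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  expect_equal(sum(s$is_leaf), 4L)
  expect_equal(s$label[s$root], "z0")
  expect_setequal(s$label[s$is_leaf], c("A", "B", "C", "D"))

  s2 <- parse_species_tree("(A,B)r;")
  expect_equal(sum(s2$is_leaf), 2L)

  expect_error(parse_species_tree("((A,B),C,D);"), "binary")
  expect_error(parse_species_tree("((A,B)x,(A,C)y)r;"), "duplicate")
  expect_error(parse_species_tree("((A,B;"), "Newick")
})

test_that("branch lengths are accepted and discarded", {
  s <- parse_species_tree("((C:0.1,D:0.2)z1:0.3,(A:1,B:2)z2:3)z0;")
  expect_equal(tree_dist(s, "C", "D"), 2L)
  expect_equal(tree_depth(s, "z0"), 0L)
})

test_that("lca queries agree with the parent-walking oracle", {
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  expect_equal(s$label[tree_lca(s, "C", "D")], "z1")
  expect_equal(tree_lca(s, s$root, 2L), s$root)

  set.seed(42)
  for (rep in 1:3) {
    tr <- random_species_tree(60)
    pairs <- cbind(sample(tr$n_nodes, 150, replace = TRUE),
                   sample(tr$n_nodes, 150, replace = TRUE))
    got <- tree_lca(tr, pairs[, 1], pairs[, 2])
    want <- mapply(naive_lca, pairs[, 1], pairs[, 2],
                   MoreArgs = list(tree = tr))
    expect_equal(got, want)
  }
})

test_that("lca agrees with ape::mrca on a shared random topology", {
  skip_if_not_installed("ape")
  set.seed(7)
  tr <- random_species_tree(40)
  ph <- ape::read.tree(text = write_newick(tr))
  m <- ape::mrca(ph)
  leaves <- leaf_labels(tr)
  for (i in 1:30) {
    ab <- sample(leaves, 2)
    got <- naive_clade(tr, tree_lca(tr, ab[1], ab[2]))
    want <- sort(ape::extract.clade(ph, m[ab[1], ab[2]])$tip.label)
    expect_equal(got, want)
  }
})

test_that("distances follow the depth formula and match the oracle", {
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  expect_equal(tree_dist(s, "z1", "z0"), 1L)
  expect_equal(tree_dist(s, "A", "A"), 0L)

  cat5 <- caterpillar_species_tree(5)
  deepest <- which(!cat5$is_leaf)[which.max(cat5$depth[!cat5$is_leaf])]
  expect_equal(tree_dist(cat5, deepest, cat5$root), 3L) # n - 2 for n = 5

  set.seed(99)
  tr <- random_species_tree(50)
  u <- sample(tr$n_nodes, 80, replace = TRUE)
  v <- sample(tr$n_nodes, 80, replace = TRUE)
  expect_equal(tree_dist(tr, u, v),
               mapply(naive_dist, u, v, MoreArgs = list(tree = tr)))
})

test_that("lca-mapping matches the per-node brute-force map", {
  f <- fig1_fixture()
  mu <- lca_map_to_species(f$g1$gene_tree, f$species,
                           reconciled_leaf_species(f$g1))
  lab <- f$species$label[mu]
  names(lab) <- f$g1$gene_tree$label
  expect_equal(lab[["x0"]], "z0")
  expect_equal(lab[["x1"]], "z1")
  expect_equal(lab[["x2"]], "z2")

  # single-species family maps everything to that leaf
  s <- parse_species_tree("(A,B)r;")
  g <- parse_gene_tree("((a1,a2)u,a3)v;")
  mu1 <- lca_map_to_species(g, s, c(a1 = "A", a2 = "A", a3 = "A"))
  expect_true(all(s$label[mu1] == "A"))

  set.seed(3)
  for (rep in 1:3) {
    p <- sim_pair(10, 3)
    r <- p$r1
    ls <- reconciled_leaf_species(r)
    expect_equal(lca_map_to_species(r$gene_tree, p$species, ls),
                 naive_lca_map(r$gene_tree, p$species, ls))
  }
})

test_that("reconciled-tree parsing resolves annotations and flags gaps", {
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  expect_error(parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B])x[&&NHX:S=z2];", s), "event")
  expect_error(parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B])x[&&NHX:S=zz:Ev=dup];", s), "species")
  expect_error(parse_reconciled_tree(
    "(a[&&NHX:S=A:Ev=dup],b[&&NHX:S=B])x[&&NHX:S=z2:Ev=dup];", s),
    "non-extant")

  # single-leaf tree: a valid trivial reconciliation
  r0 <- parse_reconciled_tree("a[&&NHX:S=A];", s)
  expect_equal(nrow(validate_reconciliation(r0)), 0L)

  # tabular annotations stand in for inline tags
  r <- parse_reconciled_tree(
    "(a,b)x;", s,
    annotations = data.frame(node = c("a", "b", "x"),
                             species = c("A", "B", "z2"),
                             event = c(NA, NA, "spec")))
  expect_equal(nrow(validate_reconciliation(r)), 0L)
  expect_equal(r$event[!r$gene_tree$is_leaf], "spec")
})

test_that("the NHX dialect round-trips reconciled trees", {
  f <- fig1_fixture()
  back <- parse_reconciled_tree(write_newick(f$g1), f$species)
  expect_true(is_isomorphic(f$g1, back))
  set.seed(5)
  r <- sim_one(8, 3)
  back <- parse_reconciled_tree(write_newick(r), r$species)
  expect_true(is_isomorphic(r, back))
})

test_that("validation reports each reconciliation rule separately", {
  f <- fig1_fixture()
  expect_equal(nrow(validate_reconciliation(f$g1)), 0L)
  expect_equal(nrow(validate_reconciliation(f$g2)), 0L)

  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  # a speciation with three children
  r <- parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B],c[&&NHX:S=C])x[&&NHX:S=z0:Ev=spec];", s)
  v <- validate_reconciliation(r)
  expect_true("speciations-separate-species" %in% v$rule)

  # child mapped strictly above its parent's species
  r <- parse_reconciled_tree(paste0(
    "((a[&&NHX:S=A],b[&&NHX:S=B])u[&&NHX:S=z0:Ev=dup],",
    "c[&&NHX:S=C])x[&&NHX:S=z1:Ev=dup];"), s)
  v <- validate_reconciliation(r)
  expect_true("time-consistency" %in% v$rule)

  # speciation whose children sit under the same species child
  r <- parse_reconciled_tree(
    "(a1[&&NHX:S=A],a2[&&NHX:S=A])x[&&NHX:S=z2:Ev=spec];", s)
  v <- validate_reconciliation(r)
  expect_true("speciations-separate-species" %in% v$rule)
})

test_that("event inference follows the lca speciation rule", {
  s <- parse_species_tree("(A,B)r;")
  g <- parse_gene_tree("(a1,a2)x;")
  mu <- lca_map_to_species(g, s, c(a1 = "A", a2 = "A"))
  expect_equal(infer_event_labels(g, s, mu)[g$root], "dup")

  g2 <- parse_gene_tree("(a,b)x;")
  mu2 <- lca_map_to_species(g2, s, c(a = "A", b = "B"))
  expect_equal(infer_event_labels(g2, s, mu2)[g2$root], "spec")

  # a polytomy can never be a speciation
  g3 <- parse_gene_tree("(a,b,b2)x;")
  mu3 <- lca_map_to_species(g3, s, c(a = "A", b = "B", b2 = "B"))
  expect_equal(infer_event_labels(g3, s, mu3)[g3$root], "dup")

  # the fig-1 y1 case: species differs from both children's species
  f <- fig1_fixture()
  g <- f$g2$gene_tree
  mu <- lca_map_to_species(g, f$species, reconciled_leaf_species(f$g2))
  ev <- infer_event_labels(g, f$species, mu)
  expect_equal(ev[match("y1", g$label)], "spec")
})

test_that("lca-reconciliation is always valid and child-order invariant", {
  set.seed(17)
  for (rep in 1:5) {
    p <- sim_pair(8, 2)
    r <- lca_reconcile(p$r1$gene_tree, p$species,
                       reconciled_leaf_species(p$r1))
    expect_equal(nrow(validate_reconciliation(r)), 0L)
  }
  # mirrored child order changes nothing semantically
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  g1 <- parse_gene_tree("((c,d)x1,(a,b)x2)x0;")
  g2 <- parse_gene_tree("((b,a)x2,(d,c)x1)x0;")
  ls <- c(a = "A", b = "B", c = "C", d = "D")
  r1 <- lca_reconcile(g1, s, ls)
  r2 <- lca_reconcile(g2, s, ls)
  expect_true(is_isomorphic(r1, r2))
  expect_equal(d_plr(r1, r2, 0.5)$d_plr, 0)
})
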