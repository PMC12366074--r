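# The PLR dissimilarity: comparability, the gene-gene m-map, directed
# components, alpha weighting, and the symmetric measure.

test_that("comparability requires shared species tree, leaves and leaf map", {
  f <- fig1_fixture()
  expect_true(are_comparable(f$g1, f$g2)$comparable)
  expect_true(are_comparable(f$g1, f$g1)$comparable)

  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  ra <- parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B])x[&&NHX:S=z2:Ev=spec];", s)
  rc <- parse_reconciled_tree(
    "(a[&&NHX:S=A],c[&&NHX:S=C])x[&&NHX:S=z0:Ev=spec];", s)
  cmp <- are_comparable(ra, rc)
  expect_false(cmp$comparable)
  expect_match(cmp$violations, "b.*c|c.*b", all = FALSE)

  # same leaves, different species tree
  s2 <- parse_species_tree("((A,B)z1,(C,D)z2)q0;")
  rb <- parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B])x[&&NHX:S=z1:Ev=spec];", s2)
  expect_true(are_comparable(ra, rb)$comparable) # same leaf-labelled topology
  s3 <- parse_species_tree("((A,C)z1,(B,D)z2)z0;")
  rd <- parse_reconciled_tree(
    "(a[&&NHX:S=A],b[&&NHX:S=B])x[&&NHX:S=z0:Ev=spec];", s3)
  expect_false(are_comparable(ra, rd)$comparable)

  # differing leaf species: refused by default, tolerated when relaxed
  re <- parse_reconciled_tree(
    "(a[&&NHX:S=B],b[&&NHX:S=A])x[&&NHX:S=z2:Ev=spec];", s)
  expect_false(are_comparable(ra, re)$comparable)
  expect_true(are_comparable(ra, re, require_leaf_species_equal = FALSE)$comparable)
  d <- d_plr(ra, re, 1, require_leaf_species_equal = FALSE)
  expect_equal(d$d_path_12, 4L) # the two swapped leaves each contribute 2
})

test_that("the m-map is the clade-lca correspondence", {
  f <- fig1_fixture()
  m <- gene_gene_lca_map(f$g1, f$g2)
  g1 <- f$g1$gene_tree
  g2 <- f$g2$gene_tree
  expect_equal(g2$label[m[match("x1", g1$label)]], "y0")

  # to itself, m is the identity
  m_self <- gene_gene_lca_map(f$g1, f$g1)
  expect_equal(as.integer(m_self), seq_len(g1$n_nodes))

  set.seed(11)
  for (rep in 1:4) {
    p <- sim_pair(10, 3)
    m12 <- gene_gene_lca_map(p$r1, p$r2)
    expect_equal(as.integer(m12), naive_m_map(p$r1, p$r2))
  }
})

test_that("building m issues fewer lca queries than G1 has edges", {
  set.seed(23)
  p <- sim_pair(12, 3)
  m <- gene_gene_lca_map(p$r1, p$r2)
  n_edges <- p$r1$gene_tree$n_nodes - 1L
  expect_lt(attr(m, "n_lca_queries"), n_edges)
})

test_that("the worked four-species example reproduces all printed values", {
  f <- fig1_fixture()
  m12 <- gene_gene_lca_map(f$g1, f$g2)
  m21 <- gene_gene_lca_map(f$g2, f$g1)
  expect_identical(d_path(f$g1, f$g2, m12), 1L)
  expect_identical(d_path(f$g2, f$g1, m21), 0L)
  expect_identical(d_lbl(f$g1, f$g2, m12), 2L)
  expect_identical(d_lbl(f$g2, f$g1, m21), 2L)
  expect_equal(d_asym(f$g1, f$g2, 0.5), 1.5)
  expect_equal(d_asym(f$g2, f$g1, 0.5), 1)
  expect_equal(d_plr(f$g1, f$g2, 0.5)$d_plr, 2.5)
})

test_that("alpha is validated and the symbolic 1/n form resolves", {
  f <- fig1_fixture()
  expect_error(d_asym(f$g1, f$g2, 1.5), "alpha")
  expect_error(d_asym(f$g1, f$g2, -0.1), "alpha")
  # n = 4 species: alpha = 1/4
  d <- d_plr(f$g1, f$g2, "1/n")
  expect_equal(d$alpha, 0.25)
  expect_equal(d$d_plr, 0.25 * 1 + 0.75 * 2 + 0.25 * 0 + 0.75 * 2)
  # alpha = 1 on identical topologies reduces to the path distance
  s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
  g <- parse_gene_tree("((c,d)x1,(a,b)x2)x0;")
  ls <- c(a = "A", b = "B", c = "C", d = "D")
  r1 <- lca_reconcile(g, s, ls)
  r2 <- new_reconciled(r1$gene_tree, s,
                       ifelse(r1$gene_tree$is_leaf, r1$mu, s$root),
                       ifelse(r1$gene_tree$is_leaf, "extant", "dup"))
  want <- sum(tree_dist(s, r1$mu, r2$mu)) # same topology: m is the identity
  expect_equal(d_plr(r1, r2, 1)$d_plr, 2 * want)
})

test_that("d_plr is zero on identity, symmetric, and infinite when incomparable", {
  set.seed(31)
  for (rep in 1:5) {
    p <- sim_pair(8, 2)
    expect_equal(d_plr(p$r1, p$r1, 0.5)$d_plr, 0)
    a <- d_plr(p$r1, p$r2, 0.37)
    b <- d_plr(p$r2, p$r1, 0.37)
    expect_identical(a$d_plr, b$d_plr)
    expect_identical(a$d_path_12, b$d_path_21)
    expect_equal(a$d_asym_12 + a$d_asym_21, a$d_plr)
    expect_lte(a$d_lbl_12, p$r1$gene_tree$n_nodes)
  }
  s <- parse_species_tree("(A,B)r;")
  ra <- parse_reconciled_tree("(a1[&&NHX:S=A],b1[&&NHX:S=B])x[&&NHX:S=r:Ev=spec];", s)
  rb <- parse_reconciled_tree("(a2[&&NHX:S=A],b1[&&NHX:S=B])x[&&NHX:S=r:Ev=spec];", s)
  d <- d_plr(ra, rb)
  expect_false(d$comparable)
  expect_identical(d$d_plr, Inf)
  # single-leaf degenerate input
  r0 <- parse_reconciled_tree("a[&&NHX:S=A];", s)
  expect_equal(d_plr(r0, r0)$d_plr, 0)
})

test_that("pairwise matrices cover all unordered pairs symmetrically", {
  set.seed(41)
  sp <- random_species_tree(6)
  gs <- random_gene_set(sp, 2)
  recs <- lapply(1:6, function(i) sim_one(species = sp, gene_set = gs))
  mat <- plr_pairwise(recs, 0.5)
  expect_equal(dim(mat), c(6L, 6L))
  expect_true(all(diag(mat) == 0))
  expect_identical(mat, t(mat))
  expect_equal(nrow(attr(mat, "components")), choose(6, 2))

  one <- plr_pairwise(recs[1], 0.5)
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 0)

  trip <- plr_pairwise(recs[c(1, 1, 1)], 0.5)
  expect_true(all(trip == 0))
})
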