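# The PLR dissimilarity: comparability, the gene-gene lca map m, the
# directed path and label components, alpha weighting, and the symmetric
# d_plr. All computations run in (near-)linear time: one postorder pass
# builds m with fewer lca queries than G1 has edges, and the component sums
# use the depth formula dist(u,v) = depth(u) + depth(v) - 2 depth(lca).

#' Check whether two reconciled gene trees are comparable
#'
#' Comparable means: same species tree (same leaf-labelled topology), same
#' gene leaf set, and (by default) every extant gene mapped to the same
#' species in both trees. The third condition may be relaxed with
#' `require_leaf_species_equal = FALSE`, in which case leaves can contribute
#' to the path component of the dissimilarity.
#'
#' @param r1,r2 `reconciled_gene_tree` objects.
#' @param require_leaf_species_equal enforce equal leaf species maps
#'   (default TRUE).
#' @return list with `comparable` (logical) and `violations` (character).
#' @export
are_comparable <- function(r1, r2, require_leaf_species_equal = TRUE) {
  stopifnot(inherits(r1, "reconciled_gene_tree"),
            inherits(r2, "reconciled_gene_tree"))
  violations <- character(0)
  if (species_tree_key(r1$species) != species_tree_key(r2$species))
    violations <- c(violations, "different species trees")
  l1 <- leaf_labels(r1$gene_tree)
  l2 <- leaf_labels(r2$gene_tree)
  if (!setequal(l1, l2)) {
    diff <- union(setdiff(l1, l2), setdiff(l2, l1))
    violations <- c(violations,
                    paste0("leaf sets differ: ", paste(diff, collapse = ", ")))
  } else if (require_leaf_species_equal) {
    s1 <- reconciled_leaf_species(r1)
    s2 <- reconciled_leaf_species(r2)
    bad <- names(s1)[s1 != s2[names(s1)]]
    if (length(bad))
      violations <- c(violations,
                      paste0("leaf species maps differ at: ",
                             paste(bad, collapse = ", ")))
  }
  list(comparable = length(violations) == 0L, violations = violations)
}

#' The gene-gene lca map between two comparable reconciled trees
#'
#' For every node `v` of the first gene tree, `m(v)` is the lowest common
#' ancestor in the second gene tree of the clade of `v` — the lowest node of
#' the target that covers all of `v`'s descendant leaves. Computed bottom-up
#' by folding the children's images through target-tree lca queries, so the
#' total number of lca queries is below the number of edges of the source
#' tree (reported as attribute `n_lca_queries`).
#'
#' @param r1 source `reconciled_gene_tree`.
#' @param r2 target `reconciled_gene_tree`, with the same leaf set.
#' @return integer vector over source gene nodes with target node ids;
#'   attribute `n_lca_queries` counts the lca queries issued.
#' @export
gene_gene_lca_map <- function(r1, r2) {
  g1 <- r1$gene_tree
  g2 <- r2$gene_tree
  l2 <- match(g1$label, g2$label) # leaf labels shared; internal labels NA-safe
  leaf2 <- integer(g1$n_nodes)
  for (v in which(g1$is_leaf)) {
    t <- match(g1$label[v], g2$label)
    if (is.na(t) || !g2$is_leaf[t])
      stop("leaf '", g1$label[v], "' absent from the target tree")
    leaf2[v] <- t
  }
  m <- integer(g1$n_nodes)
  queries <- 0L
  idx <- g2$lca_index
  first <- idx$first; ed <- idx$euler_depth; sp <- idx$sparse; eu <- idx$euler
  for (v in g1$postorder) {
    if (g1$is_leaf[v]) {
      m[v] <- leaf2[v]
      next
    }
    kids <- g1$children[[v]]
    cur <- m[kids[1L]]
    for (i in seq_along(kids)[-1L]) {
      u <- m[kids[i]]
      l <- first[cur]; r <- first[u]
      if (l > r) { t <- l; l <- r; r <- t }
      k <- floor(log2(r - l + 1L))
      half <- as.integer(2L^k)
      a <- sp[l, k + 1L]
      b <- sp[r - half + 1L, k + 1L]
      cur <- eu[if (ed[a] <= ed[b]) a else b]
      queries <- queries + 1L
    }
    m[v] <- cur
  }
  attr(m, "n_lca_queries") <- queries
  m
}

#' Directed path component of the PLR dissimilarity
#'
#' Sums, over every node `v` of the first gene tree, the species-tree path
#' length between `v`'s species and the species of its correspondent `m(v)`
#' in the second tree. Under the default comparability conditions the leaves
#' contribute zero.
#'
#' @inheritParams gene_gene_lca_map
#' @param m optional precomputed [gene_gene_lca_map()] from `r1` to `r2`.
#' @return non-negative integer.
#' @export
d_path <- function(r1, r2, m = NULL) {
  if (is.null(m)) m <- gene_gene_lca_map(r1, r2)
  s <- r1$species
  sum(tree_dist(s, r1$mu, r2$mu[m]))
}

#' Directed label component of the PLR dissimilarity
#'
#' Counts the nodes of the first gene tree whose event label differs from
#' the label of their correspondent in the second tree.
#'
#' @inheritParams d_path
#' @return non-negative integer, at most the node count of the first tree.
#' @export
d_lbl <- function(r1, r2, m = NULL) {
  if (is.null(m)) m <- gene_gene_lca_map(r1, r2)
  sum(r1$event != r2$event[m])
}

resolve_alpha <- function(alpha, species) {
  if (is.character(alpha)) {
    if (identical(alpha, "1/n")) return(1 / n_leaves(species))
    stop("alpha must be a number in [0,1] or the string \"1/n\"")
  }
  alpha <- as.numeric(alpha)
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0,1]")
  alpha
}

#' Directed asymmetric dissimilarity
#'
#' `alpha * d_path + (1 - alpha) * d_lbl` in the `r1 -> r2` direction.
#' `alpha` may be the string `"1/n"`, resolved as one over the number of
#' species-tree leaves, which keeps the quadratic path component from
#' dominating the linear label component.
#'
#' @inheritParams d_path
#' @param alpha weight in `[0,1]`, or `"1/n"`.
#' @return non-negative real.
#' @export
d_asym <- function(r1, r2, alpha = 0.5, m = NULL) {
  alpha <- resolve_alpha(alpha, r1$species)
  if (is.null(m)) m <- gene_gene_lca_map(r1, r2)
  alpha * d_path(r1, r2, m) + (1 - alpha) * d_lbl(r1, r2, m)
}

#' The symmetric PLR dissimilarity between two reconciled gene trees
#'
#' Adds the two directed asymmetric dissimilarities. Incomparable inputs are
#' not an error: the result carries `comparable = FALSE` and an infinite
#' value, keeping pairwise matrices numeric.
#'
#' @inheritParams d_asym
#' @param require_leaf_species_equal passed to [are_comparable()]; with
#'   FALSE, differing leaf species maps are tolerated and leaves may
#'   contribute to the path components.
#' @return a `plr_dissimilarity` object: both directed `d_path`/`d_lbl`
#'   integer components, both `d_asym` values, `alpha`, the symmetric
#'   `d_plr` and the `comparable` flag.
#' @examples
#' f <- fig1_fixture()
#' d_plr(f$g1, f$g2, alpha = 0.5)
#' @export
d_plr <- function(r1, r2, alpha = 0.5, require_leaf_species_equal = TRUE) {
  cmp <- are_comparable(r1, r2, require_leaf_species_equal)
  alpha_num <- resolve_alpha(alpha, r1$species)
  if (!cmp$comparable) {
    res <- list(alpha = alpha_num, comparable = FALSE,
                violations = cmp$violations,
                d_path_12 = NA_integer_, d_lbl_12 = NA_integer_,
                d_path_21 = NA_integer_, d_lbl_21 = NA_integer_,
                d_asym_12 = NA_real_, d_asym_21 = NA_real_,
                d_plr = Inf, one_gene_per_species = FALSE)
    class(res) <- "plr_dissimilarity"
    return(res)
  }
  m12 <- gene_gene_lca_map(r1, r2)
  m21 <- gene_gene_lca_map(r2, r1)
  p12 <- d_path(r1, r2, m12); l12 <- d_lbl(r1, r2, m12)
  p21 <- d_path(r2, r1, m21); l21 <- d_lbl(r2, r1, m21)
  a12 <- alpha_num * p12 + (1 - alpha_num) * l12
  a21 <- alpha_num * p21 + (1 - alpha_num) * l21
  res <- list(alpha = alpha_num, comparable = TRUE, violations = character(0),
              d_path_12 = p12, d_lbl_12 = l12,
              d_path_21 = p21, d_lbl_21 = l21,
              d_asym_12 = a12, d_asym_21 = a21,
              d_plr = a12 + a21,
              one_gene_per_species = one_gene_per_species(r1) &&
                one_gene_per_species(r2))
  class(res) <- "plr_dissimilarity"
  res
}

#' @export
print.plr_dissimilarity <- function(x, ...) {
  if (!x$comparable) {
    cat("<plr dissimilarity: incomparable trees, d_plr = Inf>\n")
    cat(" ", paste(x$violations, collapse = "; "), "\n")
    return(invisible(x))
  }
  cat(sprintf("<plr dissimilarity (alpha = %g)>\n", x$alpha))
  cat(sprintf("  d_path: %d / %d   d_lbl: %d / %d (1->2 / 2->1)\n",
              x$d_path_12, x$d_path_21, x$d_lbl_12, x$d_lbl_21))
  cat(sprintf("  d_asym: %g / %g   d_plr: %g\n",
              x$d_asym_12, x$d_asym_21, x$d_plr))
  invisible(x)
}

#' Pairwise PLR dissimilarity matrix
#'
#' Computes the `choose(n, 2)` unordered PLR values among a list of
#' reconciled gene trees. Incomparable pairs yield `Inf` entries; the
#' diagonal is zero.
#'
#' @param reconciliations list of `reconciled_gene_tree` objects.
#' @param alpha weight in `[0,1]` or `"1/n"`.
#' @param labels optional names for the matrix dimensions.
#' @return symmetric numeric matrix of `d_plr` values with attribute
#'   `components`: a long data frame with both directed integer components
#'   per unordered pair.
#' @export
plr_pairwise <- function(reconciliations, alpha = 0.5, labels = NULL) {
  n <- length(reconciliations)
  stopifnot(n >= 1L)
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  mat <- matrix(0, n, n, dimnames = list(labels, labels))
  comp <- vector("list", if (n > 1L) choose(n, 2L) else 0L)
  k <- 0L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- d_plr(reconciliations[[i]], reconciliations[[j]], alpha)
        mat[i, j] <- mat[j, i] <- d$d_plr
        k <- k + 1L
        comp[[k]] <- data.frame(
          from = labels[i], to = labels[j],
          d_path_12 = d$d_path_12, d_lbl_12 = d$d_lbl_12,
          d_path_21 = d$d_path_21, d_lbl_21 = d$d_lbl_21,
          d_plr = d$d_plr, stringsAsFactors = FALSE)
      }
    }
  }
  attr(mat, "components") <- if (k) do.call(rbind, comp) else NULL
  attr(mat, "alpha") <- resolve_alpha(alpha, reconciliations[[1L]]$species)
  mat
}
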