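# Closed-form diameters used for normalization, in the regime of one gene
# per species: H(S) (sum of root-to-internal-node distances), the PLR
# diameter 2 alpha H(S) + (1 - alpha)(2n - 2), upper bounds on the ELRF and
# LRF diameters, and a constructor for a tree pair attaining the PLR
# diameter exactly.

#' Sum of root-to-internal-node distances H(S)
#'
#' Bounds the directed path component of the PLR dissimilarity in the
#' one-gene-per-species regime, and is at most `(n-1)(n-2)/2`, with equality
#' for the caterpillar.
#'
#' @param s a `species_tree`.
#' @return non-negative integer.
#' @export
h_sum <- function(s) {
  stopifnot(inherits(s, "species_tree"))
  sum(s$depth[!s$is_leaf])
}

#' Theoretical PLR diameter for a fixed species tree
#'
#' The maximum PLR value over pairs of reconciled gene trees with exactly
#' one gene per species: `2 * alpha * H(S) + (1 - alpha) * (2n - 2)` for `n`
#' species. Maximized over species-tree shapes by the caterpillar, where it
#' equals `alpha (n-1)(n-2) + (1-alpha)(2n-2)`.
#'
#' @param s a `species_tree` with at least 2 leaves.
#' @param alpha weight in `[0,1]` or `"1/n"`.
#' @return the diameter (real).
#' @export
plr_diameter <- function(s, alpha = 0.5) {
  stopifnot(inherits(s, "species_tree"))
  n <- n_leaves(s)
  if (n < 2L) stop("diameter needs at least 2 species")
  alpha <- resolve_alpha(alpha, s)
  2 * alpha * h_sum(s) + (1 - alpha) * (2 * n - 2)
}

#' Upper bound on the ELRF diameter
#'
#' For `n >= 3` leaves and a two-element label set, any labeled tree can be
#' turned into any other with at most `3n - 8` label-respecting edge
#' contractions, extensions and label flips. Exposed as a normalization
#' constant only; the ELRF distance itself is out of scope here.
#'
#' @param n number of leaves, at least 3.
#' @return integer bound.
#' @export
elrf_diameter_bound <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("ELRF diameter bound needs n >= 3")
  3L * n - 8L
}

#' Upper bound on the LRF diameter
#'
#' As [elrf_diameter_bound()], but for the variant with unconstrained
#' contractions/extensions plus label flips: at most `2n - 5`.
#'
#' @inheritParams elrf_diameter_bound
#' @return integer bound.
#' @export
lrf_diameter_bound <- function(n) {
  n <- as.integer(n)
  if (n < 3L) stop("LRF diameter bound needs n >= 3")
  2L * n - 5L
}

#' A pair of reconciliations attaining the PLR diameter
#'
#' Both gene trees copy the species-tree topology with one gene per species
#' (genes named `<species>_1`). The first uses the lca-mapping with every
#' internal node a speciation; the second maps every internal node to the
#' species-tree root as a duplication. Their PLR dissimilarity equals
#' [plr_diameter()] exactly, for every alpha.
#'
#' @param s a binary `species_tree` with at least 2 leaves.
#' @return list with elements `g1` and `g2` (`reconciled_gene_tree`s), both
#'   valid and comparable.
#' @export
extremal_pair <- function(s) {
  stopifnot(inherits(s, "species_tree"))
  if (n_leaves(s) < 2L) stop("need at least 2 species")
  lab1 <- lab2 <- character(s$n_nodes)
  lab1[s$is_leaf] <- lab2[s$is_leaf] <- paste0(s$label[s$is_leaf], "_1")
  g1 <- gene_tree_from_parent(s$parent, lab1)
  g2 <- gene_tree_from_parent(s$parent, lab2)
  # copies share node indexing with s, so mu is positional
  ev1 <- ifelse(s$is_leaf, "extant", "spec")
  mu2 <- ifelse(s$is_leaf, seq_len(s$n_nodes), s$root)
  ev2 <- ifelse(s$is_leaf, "extant", "dup")
  list(g1 = new_reconciled(g1, s, seq_len(s$n_nodes), ev1),
       g2 = new_reconciled(g2, s, mu2, ev2))
}

#' Diameter report for a species tree
#'
#' Collects the quantities used to normalize reconciliation distances for a
#' given species tree and weight.
#'
#' @inheritParams plr_diameter
#' @return data frame with `n_species`, `alpha`, `h_sum`, `plr_diameter`,
#'   `elrf_bound`, `lrf_bound` (the RF-variant bounds are `NA` below 3
#'   leaves).
#' @export
diameter_report <- function(s, alpha = 0.5) {
  n <- n_leaves(s)
  a <- resolve_alpha(alpha, s)
  data.frame(
    n_species = n, alpha = a, h_sum = h_sum(s),
    plr_diameter = plr_diameter(s, a),
    elrf_bound = if (n >= 3L) elrf_diameter_bound(n) else NA_integer_,
    lrf_bound = if (n >= 3L) lrf_diameter_bound(n) else NA_integer_)
}

#' Normalize PLR values into [0, 1]
#'
#' Two strategies: `"theoretical"` divides by the fixed-species-tree PLR
#' diameter, which is proved only in the one-gene-per-species regime — a
#' `plr_dissimilarity` result from outside that regime is refused rather
#' than extrapolated (raw numeric input is the caller's assertion that the
#' regime holds). `"empirical_max"` divides by the maximum of a pool of
#' observed values.
#'
#' @param x a `plr_dissimilarity` result or a numeric vector of PLR values.
#' @param s the `species_tree` (theoretical mode).
#' @param alpha the weight the values were computed with (theoretical mode).
#' @param mode `"theoretical"` or `"empirical_max"`.
#' @param pool numeric vector of observed values (empirical mode); its
#'   maximum must be positive.
#' @return normalized value(s) in `[0, 1]` (values at the diameter map to 1).
#' @export
plr_normalize <- function(x, s = NULL, alpha = 0.5,
                          mode = c("theoretical", "empirical_max"),
                          pool = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "plr_dissimilarity")) {
    if (mode == "theoretical" && !x$one_gene_per_species)
      stop("theoretical normalization is only defined for one gene per species")
    x <- x$d_plr
  }
  x <- as.numeric(x)
  if (mode == "theoretical") {
    if (is.null(s)) stop("theoretical normalization needs the species tree")
    diam <- plr_diameter(s, alpha)
    if (diam <= 0) stop("zero diameter; cannot normalize")
    return(x / diam)
  }
  if (is.null(pool) || length(pool) == 0L)
    stop("empirical normalization needs a non-empty pool")
  mx <- max(pool)
  if (!is.finite(mx) || mx <= 0)
    stop("empirical pool maximum must be positive and finite")
  x / mx
}
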