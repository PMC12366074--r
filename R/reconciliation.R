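# Reconciled gene trees: (G, S, mu, l) with gene tree G, species tree S,
# gene->species map mu and event labeling l in {dup, spec, extant}.

EVENTS <- c("dup", "spec", "extant")

new_reconciled <- function(gene_tree, species, mu, event) {
  stopifnot(inherits(gene_tree, "gene_tree"), inherits(species, "species_tree"))
  mu <- as.integer(mu)
  if (length(mu) != gene_tree$n_nodes || anyNA(mu))
    stop("mu must assign a species node to every gene node")
  if (any(mu < 1L | mu > species$n_nodes)) stop("mu out of species-node range")
  if (length(event) != gene_tree$n_nodes || !all(event %in% EVENTS))
    stop("event labels must cover every gene node with dup/spec/extant")
  structure(
    list(gene_tree = gene_tree, species = species, mu = mu, event = event),
    class = "reconciled_gene_tree"
  )
}

#' Parse a reconciled gene tree
#'
#' Reads an annotated rooted Newick string in the NHX dialect of this
#' package: every node carries a species tag `S=<name>` resolvable in the
#' species tree, internal nodes carry an event tag `Ev=dup|spec`, and leaves
#' may carry `Ev=extant` (implied when absent). Alternatively, a bare Newick
#' string plus a node annotation table can be given.
#'
#' Validity of the reconciliation (time-consistency, speciation rules) is
#' not enforced here; call [validate_reconciliation()] to audit it.
#'
#' @param text annotated rooted Newick string.
#' @param species the `species_tree` the gene tree is reconciled with.
#' @param annotations optional data frame with columns `node`, `species`,
#'   `event` (node referenced by label), used for nodes lacking inline NHX
#'   tags; the two-column-per-node TSV alternate of the Newick dialect.
#' @return a `reconciled_gene_tree`.
#' @examples
#' s <- parse_species_tree("((C,D)z1,(A,B)z2)z0;")
#' g <- parse_reconciled_tree(paste0(
#'   "((c[&&NHX:S=C],d[&&NHX:S=D])x1[&&NHX:S=z1:Ev=dup],",
#'   "(a[&&NHX:S=A],b[&&NHX:S=B])x2[&&NHX:S=z2:Ev=spec])",
#'   "x0[&&NHX:S=z0:Ev=spec];"), s)
#' validate_reconciliation(g)
#' @export
parse_reconciled_tree <- function(text, species, annotations = NULL) {
  stopifnot(inherits(species, "species_tree"))
  p <- parse_newick(text)
  tree <- new_plr_tree(p$parent, p$label, subclass = "gene_tree")
  check_gene_tree(tree)

  sp_name <- rep(NA_character_, tree$n_nodes)
  ev <- rep(NA_character_, tree$n_nodes)
  for (v in seq_len(tree$n_nodes)) {
    kv <- p$annotation[[v]]
    if ("S" %in% names(kv)) sp_name[v] <- kv[["S"]]
    if ("Ev" %in% names(kv)) ev[v] <- kv[["Ev"]]
  }
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    need <- c("node", "species", "event")
    if (!all(need %in% names(annotations)))
      stop("annotations need columns: ", paste(need, collapse = ", "))
    at <- match(annotations$node, tree$label)
    if (anyNA(at))
      stop("annotation refers to unknown node(s): ",
           paste(annotations$node[is.na(at)], collapse = ", "))
    fill <- is.na(sp_name[at])
    sp_name[at[fill]] <- as.character(annotations$species[fill])
    fill <- is.na(ev[at]) & !is.na(annotations$event) &
      nzchar(as.character(annotations$event))
    ev[at[fill]] <- as.character(annotations$event[fill])
  }

  if (anyNA(sp_name))
    stop("missing species annotation on node(s): ",
         paste(tree$label[is.na(sp_name)], collapse = ", "))
  mu <- match(sp_name, species$label)
  if (anyNA(mu))
    stop("unknown species name(s): ",
         paste(unique(sp_name[is.na(mu)]), collapse = ", "))

  leaf <- tree$is_leaf
  bad_leaf_ev <- leaf & !is.na(ev) & ev != "extant"
  if (any(bad_leaf_ev))
    stop("leaf node(s) carry a non-extant event: ",
         paste(tree$label[bad_leaf_ev], collapse = ", "))
  ev[leaf] <- "extant"
  if (anyNA(ev))
    stop("missing event annotation on internal node(s): ",
         paste(tree$label[is.na(ev)], collapse = ", "))
  if (!all(ev[!leaf] %in% c("dup", "spec")))
    stop("internal events must be dup or spec")

  new_reconciled(tree, species, mu, ev)
}

#' The lca-mapping from a gene tree into a species tree
#'
#' Maps every gene-tree node to the lowest common ancestor in the species
#' tree of the species of its descendant leaves — the lowest assignment
#' permitted by the rules of reconciliation. Time-consistent by
#' construction.
#'
#' @param gene_tree a `gene_tree`.
#' @param species a `species_tree`.
#' @param leaf_species named character vector mapping every gene leaf label
#'   to a species leaf label.
#' @return integer vector over gene nodes with species node ids.
#' @export
lca_map_to_species <- function(gene_tree, species, leaf_species) {
  stopifnot(inherits(gene_tree, "gene_tree"), inherits(species, "species_tree"))
  lv <- leaf_labels(gene_tree)
  if (!all(lv %in% names(leaf_species)))
    stop("leaf(s) without an assigned species: ",
         paste(setdiff(lv, names(leaf_species)), collapse = ", "))
  sp_leaf <- match(leaf_species[lv], species$label)
  if (anyNA(sp_leaf))
    stop("unknown species for leaf(s): ",
         paste(lv[is.na(sp_leaf)], collapse = ", "))
  if (!all(species$is_leaf[sp_leaf]))
    stop("gene leaves must map to extant species (species-tree leaves)")

  mu <- integer(gene_tree$n_nodes)
  mu[which(gene_tree$is_leaf)[match(lv, leaf_labels(gene_tree))]] <- sp_leaf
  for (v in gene_tree$postorder) {
    if (gene_tree$is_leaf[v]) next
    kids <- gene_tree$children[[v]]
    cur <- mu[kids[1L]]
    for (i in seq_along(kids)[-1L]) cur <- lca_nodes(species, cur, mu[kids[i]])
    mu[v] <- cur
  }
  mu
}

#' Infer event labels from an lca-mapping
#'
#' Under the lca-mapping, an internal binary node can be a speciation if and
#' only if its species differs from the species of both of its children;
#' otherwise it must be a duplication. Non-binary internal nodes are always
#' duplications (a speciation has exactly two children). Leaves are extant.
#'
#' @inheritParams lca_map_to_species
#' @param mu the lca-mapping, as from [lca_map_to_species()].
#' @return character vector of events over gene nodes.
#' @export
infer_event_labels <- function(gene_tree, species, mu) {
  ev <- rep("extant", gene_tree$n_nodes)
  for (v in seq_len(gene_tree$n_nodes)) {
    if (gene_tree$is_leaf[v]) next
    kids <- gene_tree$children[[v]]
    if (length(kids) == 2L && !(mu[v] %in% mu[kids])) {
      ev[v] <- "spec"
    } else {
      ev[v] <- "dup"
    }
  }
  ev
}

#' Reconcile a rooted gene tree using the lca-mapping
#'
#' Convenience wrapper composing [lca_map_to_species()] and
#' [infer_event_labels()]; the result always passes
#' [validate_reconciliation()].
#'
#' @inheritParams lca_map_to_species
#' @return a `reconciled_gene_tree`.
#' @export
lca_reconcile <- function(gene_tree, species, leaf_species) {
  mu <- lca_map_to_species(gene_tree, species, leaf_species)
  new_reconciled(gene_tree, species, mu,
                 infer_event_labels(gene_tree, species, mu))
}

#' Audit a reconciled gene tree against the reconciliation requirements
#'
#' Checks the three requirements of a valid reconciliation and reports every
#' violation as data rather than throwing:
#' \describe{
#'   \item{leaves-extant}{every gene leaf maps to a species leaf and is
#'     labelled extant; internal nodes are dup or spec;}
#'   \item{time-consistency}{a child's species is a descendant (or equal) of
#'     its parent's species;}
#'   \item{speciations-separate-species}{a speciation maps to an internal
#'     species node, has exactly two children, and the children's species
#'     lie under distinct children of the speciation's species.}
#' }
#'
#' @param r a `reconciled_gene_tree`.
#' @return data frame with columns `rule`, `node`, `detail`; zero rows iff
#'   the reconciliation is valid.
#' @export
validate_reconciliation <- function(r) {
  stopifnot(inherits(r, "reconciled_gene_tree"))
  g <- r$gene_tree
  s <- r$species
  rule <- character(0); node <- character(0); detail <- character(0)
  add <- function(ru, v, de) {
    rule <<- c(rule, ru); node <<- c(node, g$label[v]); detail <<- c(detail, de)
  }

  for (v in seq_len(g$n_nodes)) {
    if (g$is_leaf[v]) {
      if (!s$is_leaf[r$mu[v]])
        add("leaves-extant", v, paste0("leaf maps to internal species '",
                                       s$label[r$mu[v]], "'"))
      if (r$event[v] != "extant")
        add("leaves-extant", v, paste0("leaf labelled '", r$event[v], "'"))
    } else if (!(r$event[v] %in% c("dup", "spec"))) {
      add("leaves-extant", v, paste0("internal node labelled '",
                                     r$event[v], "'"))
    }
  }

  non_root <- setdiff(seq_len(g$n_nodes), g$root)
  if (length(non_root)) {
    pa <- g$parent[non_root]
    ok <- is_descendant(s, r$mu[non_root], r$mu[pa])
    for (i in which(!ok))
      add("time-consistency", non_root[i],
          paste0("species '", s$label[r$mu[non_root[i]]],
                 "' not under parent's species '", s$label[r$mu[pa[i]]], "'"))
  }

  for (v in which(!g$is_leaf & r$event == "spec")) {
    sv <- r$mu[v]
    if (s$is_leaf[sv]) {
      add("speciations-separate-species", v, "speciation in an extant species")
      next
    }
    kids <- g$children[[v]]
    if (length(kids) != 2L) {
      add("speciations-separate-species", v,
          paste0("speciation with ", length(kids), " children"))
      next
    }
    sc <- s$children[[sv]]
    a <- r$mu[kids[1L]]; b <- r$mu[kids[2L]]
    sep <- (is_descendant(s, a, sc[1L]) && is_descendant(s, b, sc[2L])) ||
      (is_descendant(s, a, sc[2L]) && is_descendant(s, b, sc[1L]))
    if (!sep)
      add("speciations-separate-species", v,
          "children's species not under distinct children of the speciation's species")
  }

  data.frame(rule = rule, node = node, detail = detail,
             stringsAsFactors = FALSE)
}

# leaf label -> species label map recovered from a reconciliation
reconciled_leaf_species <- function(r) {
  g <- r$gene_tree
  leaves <- which(g$is_leaf)
  stats::setNames(r$species$label[r$mu[leaves]], g$label[leaves])
}

# TRUE iff each species leaf hosts exactly one gene leaf
one_gene_per_species <- function(r) {
  sp <- reconciled_leaf_species(r)
  sl <- leaf_labels(r$species)
  length(sp) == length(sl) && setequal(unname(sp), sl) &&
    !anyDuplicated(unname(sp))
}

#' @export
print.reconciled_gene_tree <- function(x, ...) {
  g <- x$gene_tree
  cat(sprintf("<reconciled gene tree: %d leaves, %d nodes; species tree with %d leaves>\n",
              n_leaves(g), g$n_nodes, n_leaves(x$species)))
  ev <- table(factor(x$event[!g$is_leaf], levels = c("dup", "spec")))
  cat(sprintf(" internal events: %d dup, %d spec\n", ev[["dup"]], ev[["spec"]]))
  invisible(x)
}
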