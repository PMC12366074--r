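# Newick reader/writer with NHX-style per-node comment tags.
#
# Dialect: rooted Newick; branch lengths are accepted and discarded (all
# distances in this package are edge counts); per-node annotations are
# bracketed comments of the form [&&NHX:S=<species>:Ev=dup|spec|extant]
# placed after the node name (leaf name or closing parenthesis).

parse_newick <- function(text) {
  s <- gsub("[ \t\r\n]", "", text)
  if (!nzchar(s)) stop("empty Newick string")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  pos <- 1L
  parents <- integer(0)
  labels <- character(0)
  ann <- list()

  peek <- function() if (pos <= len) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  expect <- function(ch) {
    if (peek() != ch)
      stop(sprintf("malformed Newick: expected '%s' at position %d", ch, pos))
    advance()
  }
  read_name <- function() {
    out <- character(0)
    while (pos <= len && !(chars[pos] %in% c("(", ")", ",", ":", ";", "["))) {
      out <- c(out, chars[pos])
      advance()
    }
    paste(out, collapse = "")
  }
  read_comment <- function() {
    expect("[")
    out <- character(0)
    while (pos <= len && chars[pos] != "]") {
      out <- c(out, chars[pos])
      advance()
    }
    expect("]")
    body <- paste(out, collapse = "")
    body <- sub("^&&NHX:?", "", body)
    if (!nzchar(body)) return(character(0))
    parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) stop("malformed NHX annotation: ", body)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }

  read_clade <- function(parent) {
    id <- length(parents) + 1L
    parents[id] <<- parent
    labels[id] <<- ""
    ann[[id]] <<- character(0)
    if (peek() == "(") {
      advance()
      repeat {
        read_clade(id)
        if (peek() == ",") advance() else break
      }
      expect(")")
    }
    labels[id] <<- read_name()
    repeat {
      ch <- peek()
      if (ch == "[") {
        ann[[id]] <<- c(ann[[id]], read_comment())
      } else if (ch == ":") {
        advance()
        read_name() # branch length, discarded
      } else break
    }
    id
  }

  read_clade(NA_integer_)
  if (peek() == ";") advance()
  if (pos <= len)
    stop(sprintf("malformed Newick: trailing characters at position %d", pos))
  list(parent = parents, label = labels, annotation = ann)
}

newick_string <- function(tree, annotation = NULL, internal_labels = TRUE) {
  build <- function(v) {
    lab <- if (tree$is_leaf[v] || internal_labels) tree$label[v] else ""
    tag <- ""
    if (!is.null(annotation)) {
      kv <- annotation[[v]]
      if (length(kv))
        tag <- paste0("[&&NHX:",
                      paste(names(kv), kv, sep = "=", collapse = ":"), "]")
    }
    if (tree$is_leaf[v]) return(paste0(lab, tag))
    inner <- vapply(tree$children[[v]], build, "")
    paste0("(", paste(inner, collapse = ","), ")", lab, tag)
  }
  paste0(build(tree$root), ";")
}

#' Write a tree as a Newick string
#'
#' Reconciled gene trees are written with NHX annotations (`S=` species,
#' `Ev=` event) on every node, round-tripping through
#' [parse_reconciled_tree()]. Plain trees are written as bare rooted Newick.
#'
#' @param x a species tree, gene tree, or reconciled gene tree.
#' @param ... unused.
#' @return a single Newick string.
#' @export
write_newick <- function(x, ...) UseMethod("write_newick")

#' @export
write_newick.plr_tree <- function(x, ...) newick_string(x)

#' @export
write_newick.reconciled_gene_tree <- function(x, ...) {
  g <- x$gene_tree
  s <- x$species
  annotation <- lapply(seq_len(g$n_nodes), function(v) {
    c(S = s$label[x$mu[v]], Ev = x$event[v])
  })
  newick_string(g, annotation = annotation)
}
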