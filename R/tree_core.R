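# Rooted phylogeny plumbing on top of ape's "phylo" representation.
# Edge lengths live on the child node of each edge; a root edge present in
# the input is carried along by ape but ignored by every computation here.

#' Parse a newick string into a rooted phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ape `phylo` object; polytomies are preserved, and a root edge, if present,
#' is retained in the object but ignored by all isolation metrics.
#'
#' @param text A single newick string, with branch lengths on every non-root
#'   edge. Polytomies are allowed.
#' @return A `phylo` object.
#' @examples
#' phy <- parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single newick string")
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty newick string")
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  bal <- cumsum((chars == "(") - (chars == ")"))
  if (any(bal < 0))
    stop("malformed newick: unmatched ')' at position ",
         which(bal < 0)[1L])
  if (bal[length(bal)] != 0L)
    stop("malformed newick: ", bal[length(bal)], " unclosed '(' ",
         "(first at position ", which(chars == "(")[1L], ")")
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed newick string: ", substr(txt, 1L, 60L))
  validate_tree(phy)
  phy
}

#' Validate a phylo object for isolation-metric computations
#'
#' Checks the invariants every metric relies on: a single root, unique tip
#' labels, and non-negative branch lengths present on all non-root edges.
#'
#' @param phy A `phylo` object.
#' @return `phy`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  nt <- length(phy$tip.label)
  if (nt < 2L) stop("tree must have at least 2 tips")
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(phy$edge.length))
    stop("missing branch length on ", sum(is.na(phy$edge.length)), " edge(s)")
  if (any(phy$edge.length < 0))
    stop("negative branch lengths are not allowed")
  # every non-root node has exactly one parent
  if (anyDuplicated(phy$edge[, 2L]))
    stop("a node has more than one parent edge")
  invisible(phy)
}

#' Write a phylogeny as a canonical newick string
#'
#' Emits newick with a deterministic child order (children sorted by their
#' lexicographically smallest descendant tip label), so that byte-identical
#' output is obtained from topologically identical trees regardless of the
#' internal edge ordering.
#'
#' @param phy A `phylo` object.
#' @param file Optional path; when given the string is written there.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(phy, file = NULL, digits = 12) {
  validate_tree(phy)
  ix <- tree_index(phy)
  kids <- ix$children
  minlab <- character(ix$ntip + ix$nnode)
  minlab[seq_len(ix$ntip)] <- phy$tip.label
  # postorder so children are resolved before parents
  for (nd in ix$postorder_nodes) {
    if (nd > ix$ntip) minlab[nd] <- min(minlab[kids[[nd]]])
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  build <- function(nd) {
    if (nd <= ix$ntip) {
      s <- phy$tip.label[nd]
    } else {
      ch <- kids[[nd]]
      ch <- ch[order(minlab[ch])]
      s <- paste0("(", paste(vapply(ch, build, ""), collapse = ","), ")")
    }
    if (nd != ix$root) s <- paste0(s, ":", fmt(ix$elen[nd]))
    s
  }
  out <- paste0(build(ix$root), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param phy A `phylo` object.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns in
#'   `phy$tip.label` order, entry (i, j) the sum of branch lengths on the
#'   unique path between tips i and j.
#' @export
patristic_matrix <- function(phy) {
  validate_tree(phy)
  m <- ape::cophenetic.phylo(phy)
  # cophenetic.phylo returns tip-label order; enforce it explicitly
  m[phy$tip.label, phy$tip.label, drop = FALSE]
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip depths must agree to within `tol` relative to the maximum
#' depth. A root edge, if present, is not counted.
#'
#' @param phy A `phylo` object.
#' @param tol Relative tolerance on the depth range (default `1e-6`).
#' @return Logical flag.
#' @export
is_ultrametric <- function(phy, tol = 1e-6) {
  validate_tree(phy)
  depth <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  dmax <- max(depth)
  if (dmax == 0) return(TRUE)
  (dmax - min(depth)) <= tol * dmax
}

#' Nested complete clades containing a target tip
#'
#' Returns the sequence of complete subtrees rooted at each successive
#' ancestor of `tip`, ordered smallest (the tip's immediate parent clade) to
#' the full tree. Used to study how isolation scores scale with clade size.
#'
#' @param phy A `phylo` object.
#' @param tip A tip label present in the tree.
#' @return A list of `phylo` objects, each containing `tip`.
#' @export
nested_clades <- function(phy, tip) {
  validate_tree(phy)
  it <- match(tip, phy$tip.label)
  if (is.na(it)) stop("unknown tip label: ", tip)
  ix <- tree_index(phy)
  anc <- integer(0)
  nd <- ix$parent[it]
  while (nd != 0L) {
    anc <- c(anc, nd)
    nd <- ix$parent[nd]
  }
  lapply(anc, function(a) {
    if (a == ix$root) phy else ape::extract.clade(phy, a)
  })
}

# ---- internal traversal index -------------------------------------------

# Precomputes, once per tree, everything the metrics need:
#   parent[v]  parent node (0 for root)
#   elen[v]    length of the edge above v (0 for root)
#   ndesc[v]   number of tips descending from v (tips count themselves)
#   nkids[v]   number of daughter lineages at v
#   preorder   edge traversal with parents before children (2-col matrix)
tree_index <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  root <- nt + 1L
  E <- phy$edge
  parent <- integer(nt + nn)
  parent[E[, 2L]] <- E[, 1L]
  elen <- numeric(nt + nn)
  if (!is.null(phy$edge.length)) elen[E[, 2L]] <- phy$edge.length
  po <- ape::reorder.phylo(phy, "postorder")
  ndesc <- integer(nt + nn)
  ndesc[seq_len(nt)] <- 1L
  pe <- po$edge
  for (k in seq_len(nrow(pe)))
    ndesc[pe[k, 1L]] <- ndesc[pe[k, 1L]] + ndesc[pe[k, 2L]]
  nkids <- tabulate(E[, 1L], nbins = nt + nn)
  children <- split(E[, 2L], factor(E[, 1L], levels = seq_len(nt + nn)))
  list(ntip = nt, nnode = nn, root = root, parent = parent, elen = elen,
       ndesc = ndesc, nkids = nkids,
       preorder = pe[rev(seq_len(nrow(pe))), , drop = FALSE],
       postorder = pe,
       postorder_nodes = c(pe[, 2L][pe[, 2L] > nt], root),
       children = children)
}

# Total tree length (sum of all branch lengths, root edge excluded).
tree_length <- function(phy) sum(phy$edge.length)
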