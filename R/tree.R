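#' Indexed rooted binary tree
#'
#' Internal tree representation used throughout the package. Nodes are
#' indexed 1..2N-1 in post-order (every child has a smaller index than its
#' parent; the root is node 2N-1). Each non-root node carries the length of
#' the branch connecting it to its parent, in the same time unit as the
#' gain/loss rates.
#'
#' @param phy an \code{ape::phylo} object: rooted, strictly binary, with
#'   strictly positive branch lengths on every edge.
#' @return an object of class \code{gcevo_tree}: a list with elements
#'   \code{n_tip}, \code{n_node}, \code{parent} (integer, \code{NA} at the
#'   root), \code{children} (\code{n_node} x 2 integer matrix, \code{NA} rows
#'   for tips), \code{brlen} (numeric, \code{NA} at the root), \code{is_tip}
#'   (logical) and \code{labels} (species names at tips, \code{"n<idx>"} at
#'   internal nodes).
#' @export
as_gcevo_tree <- function(phy) {
  if (inherits(phy, "gcevo_tree")) return(phy)
  if (!inherits(phy, "phylo")) stop("expected an 'ape' phylo object")
  n_tip <- length(phy$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 leaves")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  n_ape <- n_tip + phy$Nnode
  deg_out <- tabulate(phy$edge[, 1L], nbins = n_ape)
  if (any(deg_out[(n_tip + 1L):n_ape] != 2L)) {
    stop("tree must be strictly binary: polytomies (or unifurcations) found; ",
         "resolve them before use")
  }
  if (anyDuplicated(phy$tip.label)) stop("leaf labels must be unique")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop("all branches must have lengths")
  }
  if (any(phy$edge.length <= 0)) {
    stop("all branch lengths must be > 0; use add_pseudo_branch_length() ",
         "to add a small pseudo length to every branch")
  }

  # children of each ape node
  kid <- matrix(NA_integer_, n_ape, 2L)
  blen_ape <- rep(NA_real_, n_ape)  # length of branch above each ape node
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; c <- phy$edge[e, 2L]
    kid[p, if (is.na(kid[p, 1L])) 1L else 2L] <- c
    blen_ape[c] <- phy$edge.length[e]
  }
  root_ape <- n_tip + 1L

  # iterative post-order traversal
  order_ape <- integer(n_ape)
  pos <- 0L
  stack <- integer(2L * n_ape); sexp <- logical(2L * n_ape)
  top <- 1L; stack[1L] <- root_ape; sexp[1L] <- FALSE
  while (top > 0L) {
    nd <- stack[top]; expanded <- sexp[top]; top <- top - 1L
    if (nd <= n_tip || expanded) {
      pos <- pos + 1L
      order_ape[pos] <- nd
    } else {
      top <- top + 1L; stack[top] <- nd; sexp[top] <- TRUE
      top <- top + 1L; stack[top] <- kid[nd, 2L]; sexp[top] <- FALSE
      top <- top + 1L; stack[top] <- kid[nd, 1L]; sexp[top] <- FALSE
    }
  }
  new_idx <- integer(n_ape)
  new_idx[order_ape] <- seq_len(n_ape)

  n_node <- n_ape
  parent <- rep(NA_integer_, n_node)
  children <- matrix(NA_integer_, n_node, 2L)
  brlen <- rep(NA_real_, n_node)
  labels <- character(n_node)
  is_tip <- logical(n_node)
  for (a in seq_len(n_ape)) {
    i <- new_idx[a]
    if (a <= n_tip) {
      is_tip[i] <- TRUE
      labels[i] <- phy$tip.label[a]
    } else {
      children[i, ] <- sort(new_idx[kid[a, ]])
      labels[i] <- paste0("n", i)
    }
    brlen[i] <- blen_ape[a]
  }
  for (i in which(!is_tip)) parent[children[i, ]] <- i

  structure(list(n_tip = n_tip, n_node = n_node, parent = parent,
                 children = children, brlen = brlen, is_tip = is_tip,
                 labels = labels),
            class = "gcevo_tree")
}

#' @export
print.gcevo_tree <- function(x, ...) {
  cat("gcevo_tree:", x$n_tip, "leaves,", x$n_node - x$n_tip,
      "internal nodes (post-order indexed, root = node", x$n_node, ")\n")
  invisible(x)
}

tree_root <- function(tree) tree$n_node

tip_labels <- function(tree) tree$labels[tree$is_tip]

internal_nodes <- function(tree) which(!tree$is_tip)

# nodes having a parent branch, in post-order
branch_nodes <- function(tree) seq_len(tree$n_node - 1L)

#' Convert back to an ape phylo object
#'
#' @param tree a \code{gcevo_tree}.
#' @param internal_labels if \code{TRUE}, attach the \code{"n<idx>"} internal
#'   node labels so the exported Newick identifies ancestral nodes.
#' @return an \code{ape::phylo} object.
#' @export
gcevo_tree_to_phylo <- function(tree, internal_labels = FALSE) {
  n_tip <- tree$n_tip
  ints <- internal_nodes(tree)
  # ape node ids: tips 1..N in our post-order tip order, internals N+1.., root first
  tip_ids <- integer(tree$n_node)
  tip_ids[tree$is_tip] <- seq_len(n_tip)
  root <- tree_root(tree)
  int_order <- c(root, setdiff(rev(ints), root))  # root first, then others
  tip_ids[int_order] <- n_tip + seq_along(int_order)
  edge <- matrix(0L, tree$n_node - 1L, 2L)
  elen <- numeric(tree$n_node - 1L)
  e <- 0L
  for (i in branch_nodes(tree)) {
    e <- e + 1L
    edge[e, ] <- c(tip_ids[tree$parent[i]], tip_ids[i])
    elen[e] <- tree$brlen[i]
  }
  phy <- list(edge = edge, edge.length = elen,
              tip.label = tree$labels[tree$is_tip],
              Nnode = length(ints))
  if (internal_labels) {
    nl <- character(length(ints))
    nl[tip_ids[int_order] - n_tip] <- tree$labels[int_order]
    phy$node.label <- nl
  }
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Read a rooted binary Newick tree
#'
#' @param path path to a Newick file.
#' @param pseudo_length optional positive constant added to every branch
#'   before validation, rescuing trees with zero-length branches (see
#'   [add_pseudo_branch_length()]).
#' @return a [as_gcevo_tree()] object.
#' @export
read_newick <- function(path, pseudo_length = NULL) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick file: ", path)
  if (!is.null(pseudo_length)) phy <- add_pseudo_branch_length(phy, pseudo_length)
  as_gcevo_tree(phy)
}

#' Write a tree to Newick
#'
#' @param tree a \code{gcevo_tree}.
#' @param path output path.
#' @param internal_labels annotate internal nodes with \code{"n<idx>"} labels.
#' @export
write_newick <- function(tree, path, internal_labels = FALSE) {
  phy <- gcevo_tree_to_phylo(tree, internal_labels = internal_labels)
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Add a pseudo length to every branch
#'
#' Rescues trees containing zero-length branches (common after collapsing
#' strain-level duplicates) by adding a small constant to all branches, so
#' topology and relative lengths are preserved while the positivity
#' requirement is met.
#'
#' @param tree a \code{gcevo_tree} or an \code{ape::phylo} (the latter may
#'   contain zero-length branches, so trees that fail validation can still be
#'   rescued).
#' @param eps positive length added to every branch.
#' @return the tree with every branch length increased by \code{eps}, same
#'   class as the input.
#' @export
add_pseudo_branch_length <- function(tree, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0) {
    stop("'eps' must be a single positive number")
  }
  if (inherits(tree, "gcevo_tree")) {
    bn <- branch_nodes(tree)
    tree$brlen[bn] <- tree$brlen[bn] + eps
    return(tree)
  }
  if (inherits(tree, "phylo")) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths at all")
    tree$edge.length <- tree$edge.length + eps
    return(tree)
  }
  stop("expected a gcevo_tree or phylo object")
}
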