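# Joint maximum-likelihood reconstruction of ancestral copy numbers:
# max-product dynamic programming up the tree with back-pointers (the
# tree analogue of the Viterbi algorithm), one downward trace per family.

#' MAP cluster assignment
#'
#' @param gamma_row responsibility vector of one family (sums to 1).
#' @return index of the most probable cluster; ties break toward the lower
#'   index.
#' @export
assign_cluster <- function(gamma_row) {
  which.max(gamma_row)
}

# vectorized max-product pass for many families under one cluster.
# D: species x families (states 0..lmax); returns states matrix
# n_node x L (leaves clamped to the data).
viterbi_engine <- function(D, R_k, pi_k, tree) {
  s <- R_k$lmax + 1L
  L <- ncol(D)
  cb <- cluster_branch_mats(R_k, tree)
  logP <- lapply(cb$P, function(P) if (is.null(P)) NULL else log(P))
  tip_row <- cumsum(tree$is_tip)
  root <- tree_root(tree)
  subtree <- vector("list", tree$n_node)  # log score of subtree given own state
  upmsg <- vector("list", tree$n_node)    # max-product message to parent (s x L)
  ptr <- vector("list", tree$n_node)      # best own state per parent state (s x L)
  for (m in seq_len(tree$n_node)) {
    if (tree$is_tip[m]) {
      sc <- matrix(-Inf, s, L)
      sc[cbind(D[tip_row[m], ] + 1L, seq_len(L))] <- 0
    } else {
      ch <- tree$children[m, ]
      sc <- upmsg[[ch[1L]]] + upmsg[[ch[2L]]]
    }
    subtree[[m]] <- sc
    if (m < root) {
      up <- matrix(0, s, L)
      pt <- matrix(1L, s, L)
      for (a in seq_len(s)) {
        w <- logP[[m]][a, ] + sc          # s x L: candidate own states
        pt[a, ] <- max.col(t(w), ties.method = "first")
        up[a, ] <- w[cbind(pt[a, ], seq_len(L))]
      }
      upmsg[[m]] <- up
      ptr[[m]] <- pt
    }
  }
  states <- matrix(0L, tree$n_node, L)
  root_sc <- log(pi_k) + subtree[[root]]
  states[root, ] <- max.col(t(root_sc), ties.method = "first") - 1L
  for (m in rev(seq_len(tree$n_node - 1L))) {
    if (tree$is_tip[m]) {
      states[m, ] <- D[tip_row[m], ]
    } else {
      pa <- states[tree$parent[m], ]
      states[m, ] <- ptr[[m]][cbind(pa + 1L, seq_len(L))] - 1L
    }
  }
  states
}

#' Jointly most likely ancestral states for one family
#'
#' Maximizes \code{pi_k(x_root) * prod_branches P(x_child | x_parent, t_m)}
#' over all internal-node state assignments with the leaves clamped to the
#' observed copy numbers, via a max-product upward pass with back-pointers
#' and a single downward trace. Ties break deterministically toward the
#' lower state.
#'
#' @inheritParams family_inside
#' @return integer vector of states (0..lmax) for all nodes in post-order
#'   indexing (leaf entries equal the input data).
#' @export
viterbi_states <- function(D_l, R_k, pi_k, tree) {
  if (!is.null(names(D_l))) D_l <- D_l[tip_labels(tree)]
  if (any(D_l < 0 | D_l > R_k$lmax)) stop("leaf states must lie in 0..lmax")
  drop(viterbi_engine(matrix(as.integer(D_l), ncol = 1L), R_k, pi_k, tree))
}

#' Reconstruct the gene-content history of every family
#'
#' Assigns each family to its maximum-a-posteriori cluster, reconstructs the
#' jointly most likely ancestral copy numbers under that cluster's generator,
#' and derives per-branch gain/loss event counts from state differences
#' (gains = max(child - parent, 0), losses = max(parent - child, 0); the
#' minimal-event reading of a +-1-step chain).
#'
#' @param D species x families [ortholog_table()] aligned (or alignable) to
#'   the tree; entries above \code{theta$lmax} are clipped.
#' @param tree a [as_gcevo_tree()] tree.
#' @param theta fitted [mixture_params()].
#' @return an object of class \code{gcevo_history}: list with \code{cluster}
#'   (per-family MAP cluster), \code{states} (n_node x L matrix of copy
#'   numbers, leaves included), \code{gains}/\code{losses} (n_node x L
#'   per-branch event counts, zero row at the root), per-family totals
#'   \code{total_gains}/\code{total_losses}, \code{family_loglik} and the
#'   \code{tree}.
#' @export
reconstruct_all <- function(D, tree, theta) {
  D <- align_table_tree(D, tree)
  D <- suppressMessages(clip_copy_numbers(D, theta$lmax))
  Dm <- unclass(D)
  L <- ncol(Dm)
  ll <- cluster_logliks(theta, Dm, tree)
  log_post <- ll + rep(log(theta$phi), each = L)
  mx <- apply(log_post, 1L, max)
  ex <- exp(log_post - mx)
  gamma <- ex / rowSums(ex)
  family_loglik <- mx + log(rowSums(ex))
  cluster <- apply(gamma, 1L, assign_cluster)
  view <- cluster_view(theta)
  states <- matrix(0L, tree$n_node, L)
  for (k in sort(unique(cluster))) {
    idx <- which(cluster == k)
    states[, idx] <- viterbi_engine(Dm[, idx, drop = FALSE],
                                    view[[k]]$R, view[[k]]$pi, tree)
  }
  gains <- matrix(0L, tree$n_node, L)
  losses <- matrix(0L, tree$n_node, L)
  for (m in branch_nodes(tree)) {
    d <- states[m, ] - states[tree$parent[m], ]
    gains[m, ] <- pmax(d, 0L)
    losses[m, ] <- pmax(-d, 0L)
  }
  structure(list(cluster = cluster, states = states,
                 gains = gains, losses = losses,
                 total_gains = colSums(gains),
                 total_losses = colSums(losses),
                 family_loglik = family_loglik,
                 family = colnames(D), tree = tree),
            class = "gcevo_history")
}

#' @export
print.gcevo_history <- function(x, ...) {
  cat("gcevo_history:", length(x$cluster), "families,",
      sum(!x$tree$is_tip), "ancestral nodes\n")
  cat("total events:", sum(x$total_gains), "gains,",
      sum(x$total_losses), "losses\n")
  invisible(x)
}

#' Per-family gain/loss event counts
#'
#' @param history a [reconstruct_all()] result.
#' @return data.frame with columns \code{family}, \code{gains},
#'   \code{losses}.
#' @export
count_events <- function(history) {
  stopifnot(inherits(history, "gcevo_history"))
  data.frame(family = history$family,
             gains = history$total_gains,
             losses = history$total_losses,
             row.names = NULL)
}

#' Write a reconstruction to TSV
#'
#' One row per family: FamilyID, cluster, loglik, one column per internal
#' node (labelled \code{n<idx>} as in the annotated Newick export of
#' [write_newick()]), then total gains and losses.
#'
#' @param history a [reconstruct_all()] result.
#' @param path output path.
#' @export
write_reconstruction <- function(history, path) {
  tree <- history$tree
  ints <- internal_nodes(tree)
  anc <- t(history$states[ints, , drop = FALSE])
  colnames(anc) <- tree$labels[ints]
  df <- data.frame(FamilyID = history$family,
                   cluster = history$cluster,
                   loglik = history$family_loglik,
                   anc,
                   total_gains = history$total_gains,
                   total_losses = history$total_losses,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
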