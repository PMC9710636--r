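# Forward simulator: perfect binary topologies, Yule branch lengths, and
# Gillespie simulation of the truncated gain/loss chain along every branch,
# with full ground truth (cluster, node states, per-branch event counts).

#' Perfect binary tree topology
#'
#' @param n_leaves number of leaves; must be a power of two. Leaves are
#'   labelled \code{s1..sN}.
#' @return a [as_gcevo_tree()] tree with unit branch lengths (use
#'   [yule_branch_lengths()] to draw lengths).
#' @export
perfect_binary_tree <- function(n_leaves) {
  h <- log2(n_leaves)
  if (n_leaves < 2 || h != round(h)) {
    stop("'n_leaves' must be a power of two >= 2")
  }
  newick <- "s"
  for (d in seq_len(h)) newick <- paste0("(", newick, ":1,", newick, ":1)")
  phy <- ape::read.tree(text = paste0(newick, ";"))
  phy$tip.label <- paste0("s", seq_len(n_leaves))
  as_gcevo_tree(phy)
}

#' Yule-process branch lengths on a fixed topology
#'
#' Draws speciation waiting times from a pure-birth (Yule) process: while k
#' lineages exist the time to the next split is Exponential(k * birth_rate).
#' The root is the first split; subsequent split times are assigned to the
#' internal nodes in level order (so times increase from root to tips), and
#' all leaves sit at the present, making the tree ultrametric. Uses the
#' current R random stream.
#'
#' @param topology a [as_gcevo_tree()] tree (its branch lengths are ignored).
#' @param birth_rate positive Yule birth rate lambda.
#' @return the tree with freshly drawn, strictly positive branch lengths.
#' @export
yule_branch_lengths <- function(topology, birth_rate) {
  if (!is.numeric(birth_rate) || length(birth_rate) != 1L || birth_rate <= 0) {
    stop("'birth_rate' must be a single positive number")
  }
  tree <- topology
  N <- tree$n_tip
  # waiting times while k = 2..N lineages exist
  waits <- stats::rexp(N - 1L, rate = (2:N) * birth_rate)
  split_times <- c(0, cumsum(waits[-(N - 1L)]))  # N-1 split times, root at 0
  present <- sum(waits)
  # level-order (BFS) assignment of split times to internal nodes
  root <- tree_root(tree)
  bfs <- root
  i <- 1L
  while (i <= length(bfs)) {
    m <- bfs[i]
    if (!tree$is_tip[m]) bfs <- c(bfs, tree$children[m, ])
    i <- i + 1L
  }
  node_time <- rep(present, tree$n_node)
  node_time[bfs[!tree$is_tip[bfs]]] <- split_times
  for (m in branch_nodes(tree)) {
    tree$brlen[m] <- node_time[m] - node_time[tree$parent[m]]
  }
  if (any(tree$brlen[branch_nodes(tree)] <= 0)) {
    stop("internal error: nonpositive Yule branch length")
  }
  tree
}

# Gillespie simulation of the truncated chain along one branch.
# Returns c(end_state, gains, losses); states 0..lmax.
simulate_branch <- function(state, gains_vec, losses_vec, lmax, t) {
  time <- 0
  g <- 0L; l <- 0L
  repeat {
    up <- if (state < lmax) gains_vec[state + 1L] else 0
    down <- if (state > 0L) losses_vec[state] else 0
    total <- up + down
    if (total <= 0) break
    time <- time + stats::rexp(1L, total)
    if (time > t) break
    if (stats::runif(1L) < up / total) {
      state <- state + 1L; g <- g + 1L
    } else {
      state <- state - 1L; l <- l + 1L
    }
  }
  c(state, g, l)
}

#' Simulate one gene family
#'
#' Draws a cluster from \code{phi}, a root copy number from that cluster's
#' root distribution, and evolves the copy number along every branch by
#' Gillespie simulation of the truncated (lmax+1)-state chain (the same
#' generator the inference uses, so states are hard-bounded at 0 and lmax by
#' construction). Uses the current R random stream.
#'
#' @param theta a [mixture_params()] object.
#' @param tree a [as_gcevo_tree()] tree with positive branch lengths.
#' @return list with \code{cluster}, \code{states} (per-node copy numbers in
#'   post-order indexing), \code{gains} and \code{losses} (true per-branch
#'   event counts).
#' @export
simulate_family <- function(theta, tree) {
  view <- cluster_view(theta)
  k <- sample.int(theta$K, 1L, prob = theta$phi)
  cl <- view[[k]]
  lmax <- theta$lmax
  gv <- rate_gains(cl$R)
  lv <- rate_losses(cl$R)
  states <- integer(tree$n_node)
  gains <- integer(tree$n_node)
  losses <- integer(tree$n_node)
  root <- tree_root(tree)
  states[root] <- sample.int(lmax + 1L, 1L, prob = cl$pi) - 1L
  for (m in rev(branch_nodes(tree))) {   # parents before children
    res <- simulate_branch(states[tree$parent[m]], gv, lv, lmax,
                           tree$brlen[m])
    states[m] <- res[1L]
    gains[m] <- res[2L]
    losses[m] <- res[3L]
  }
  list(cluster = k, states = states, gains = gains, losses = losses)
}

#' Simulate an ortholog table with recorded ground truth
#'
#' @inheritParams simulate_family
#' @param L number of gene families.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class \code{gcevo_sim}: list with \code{table} (a
#'   species x families [ortholog_table()]) and \code{truth}, a list holding
#'   \code{theta}, per-family \code{cluster}, \code{states} (n_node x L),
#'   \code{gains}/\code{losses} (n_node x L true per-branch event counts) and
#'   per-family \code{total_gains}/\code{total_losses}.
#' @export
simulate_dataset <- function(theta, tree, L, seed = NULL) {
  if (L < 1L) stop("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(0L, tree$n_node, L)
  gains <- matrix(0L, tree$n_node, L)
  losses <- matrix(0L, tree$n_node, L)
  cluster <- integer(L)
  for (l in seq_len(L)) {
    fam <- simulate_family(theta, tree)
    cluster[l] <- fam$cluster
    states[, l] <- fam$states
    gains[, l] <- fam$gains
    losses[, l] <- fam$losses
  }
  counts <- states[tree$is_tip, , drop = FALSE]
  rownames(counts) <- tip_labels(tree)
  colnames(counts) <- paste0("fam", seq_len(L))
  structure(list(table = ortholog_table(counts),
                 truth = list(theta = theta, cluster = cluster,
                              states = states, gains = gains,
                              losses = losses,
                              total_gains = colSums(gains),
                              total_losses = colSums(losses)),
                 tree = tree),
            class = "gcevo_sim")
}

#' @export
print.gcevo_sim <- function(x, ...) {
  cat("gcevo_sim:", ncol(x$table), "families on", nrow(x$table),
      "species (", toupper(x$truth$theta$kind), "+",
      toupper(x$truth$theta$hetero), ", K =", x$truth$theta$K, ")\n")
  invisible(x)
}

#' Write simulation ground truth to TSV
#'
#' One row per family: FamilyID, true cluster, the true state at every node
#' (\code{n<idx>} columns for internal nodes, species names for leaves) and
#' total true gains/losses.
#'
#' @param sim a [simulate_dataset()] result.
#' @param path output path.
#' @export
write_truth <- function(sim, path) {
  tree <- sim$tree
  st <- t(sim$truth$states)
  colnames(st) <- tree$labels
  df <- data.frame(FamilyID = colnames(sim$table),
                   cluster = sim$truth$cluster, st,
                   total_gains = sim$truth$total_gains,
                   total_losses = sim$truth$total_losses,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
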