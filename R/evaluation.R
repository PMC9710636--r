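# Evaluation metrics and experiment harnesses: relative errors with IQRs,
# ancestral-state accuracy (copy-number and presence/absence), event-count
# correlation, normalized cluster evolutionary rates, and holdout splits.

# enumerate permutations of 1..n (n is small: K <= ~8)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# free-rate vector of a cluster (gains then losses)
cluster_rate_vector <- function(cl) c(rate_gains(cl$R), rate_losses(cl$R))

#' Align cluster labels of two mixtures
#'
#' Cluster labels are unidentifiable; this finds the permutation of
#' \code{theta_hat}'s clusters minimizing the total absolute difference of
#' free gain/loss rates against \code{theta_true}.
#'
#' @param theta_hat,theta_true [mixture_params()] objects with equal K.
#' @return integer permutation \code{p} such that cluster \code{p[k]} of
#'   \code{theta_hat} corresponds to cluster \code{k} of \code{theta_true}.
#' @export
match_clusters <- function(theta_hat, theta_true) {
  if (theta_hat$K != theta_true$K) stop("mixtures must have equal K")
  vh <- lapply(cluster_view(theta_hat), cluster_rate_vector)
  vt <- lapply(cluster_view(theta_true), cluster_rate_vector)
  cost <- outer(seq_len(theta_true$K), seq_len(theta_hat$K),
                Vectorize(function(i, j) sum(abs(vt[[i]] - vh[[j]]))))
  perms <- permutations(theta_true$K)
  tot <- apply(perms, 1L, function(p) sum(cost[cbind(seq_len(theta_true$K), p)]))
  perms[which.min(tot), ]
}

#' Relative estimation errors per parameter block
#'
#' Element-wise \code{100 * (theta_hat - theta) / theta} for every parameter
#' with nonzero true value, grouped into blocks (R rates, pi, phi, r,
#' gamma shape), after aligning cluster labels with [match_clusters()]. The
#' spread of each block is summarized by its interquartile range (75th minus
#' 25th percentile, linear interpolation).
#'
#' @inheritParams match_clusters
#' @return list with \code{errors} (named list of numeric vectors per block)
#'   and \code{iqr} (named numeric vector).
#' @export
relative_errors <- function(theta_hat, theta_true) {
  p <- match_clusters(theta_hat, theta_true)
  vh <- cluster_view(theta_hat)[p]
  vt <- cluster_view(theta_true)
  rel <- function(hat, true) {
    keep <- true != 0
    if (any(!keep)) warning("parameters with true value 0 excluded from relative errors")
    100 * (hat[keep] - true[keep]) / true[keep]
  }
  errors <- list()
  errors$R <- rel(unlist(lapply(vh, cluster_rate_vector)),
                  unlist(lapply(vt, cluster_rate_vector)))
  errors$pi <- rel(unlist(lapply(vh, `[[`, "pi")),
                   unlist(lapply(vt, `[[`, "pi")))
  errors$phi <- rel(theta_hat$phi[p], theta_true$phi)
  if (!is.null(theta_hat$r) && !is.null(theta_true$r)) {
    errors$r <- rel(theta_hat$r[p], theta_true$r)
  }
  if (!is.null(theta_hat$gamma_shape) && !is.null(theta_true$gamma_shape)) {
    errors$alpha <- rel(theta_hat$gamma_shape, theta_true$gamma_shape)
  }
  iqr <- vapply(errors, function(e) {
    if (length(e) < 2L) 0 else diff(stats::quantile(e, c(0.25, 0.75), type = 7, names = FALSE))
  }, 0)
  list(errors = errors, iqr = iqr)
}

#' Ancestral reconstruction accuracy
#'
#' Percent of (family, internal node) pairs whose reconstructed state equals
#' the simulated truth; with \code{presence_absence = TRUE} states are first
#' collapsed to absent (0) vs present (>= 1). \code{per_family = TRUE}
#' instead scores each family 1 only if all of its ancestral nodes are
#' correct (the stricter all-nodes reading).
#'
#' @param history a [reconstruct_all()] result.
#' @param truth the \code{truth} element of a [simulate_dataset()] result (or
#'   any list with an n_node x L \code{states} matrix).
#' @param presence_absence collapse states to absence/presence first.
#' @param per_family score whole families rather than (family, node) pairs.
#' @return accuracy in percent (0..100).
#' @export
ancestral_accuracy <- function(history, truth, presence_absence = FALSE,
                               per_family = FALSE) {
  tree <- history$tree
  est <- history$states[!tree$is_tip, , drop = FALSE]
  tru <- truth$states[!tree$is_tip, , drop = FALSE]
  if (!all(dim(est) == dim(tru))) stop("history and truth shapes differ")
  if (presence_absence) {
    est <- est >= 1L
    tru <- tru >= 1L
  }
  hit <- est == tru
  100 * if (per_family) mean(colSums(!hit) == 0L) else mean(hit)
}

#' Correlation of reconstructed and true event counts
#'
#' Pearson correlation across families between total (gains + losses) event
#' counts in the reconstructed history and in the simulation truth, reported
#' on a 0-100 scale.
#'
#' @inheritParams ancestral_accuracy
#' @return correlation x 100, or \code{NA} if either vector has zero
#'   variance.
#' @export
event_count_correlation <- function(history, truth) {
  est <- history$total_gains + history$total_losses
  tru <- truth$total_gains + truth$total_losses
  if (length(est) != length(tru)) stop("history and truth shapes differ")
  if (length(est) < 3L || stats::sd(est) == 0 || stats::sd(tru) == 0) {
    warning("event-count correlation undefined (zero variance)")
    return(NA_real_)
  }
  100 * stats::cor(est, tru)
}

#' Normalized cluster evolutionary rates
#'
#' For each cluster, the magnitude of the root-distribution-weighted total
#' exit rate \code{|sum_i pi_k(i) [R_k]_ii|}, divided by the minimum across
#' clusters, quantifying how much faster gene content evolves in each cluster
#' than in the slowest one.
#'
#' @param theta a [mixture_params()] object (any heterogeneity kind; for
#'   shared-pi models the shared root distribution is used for every
#'   cluster).
#' @return numeric vector of K rates, minimum exactly 1.
#' @export
normalized_cluster_rates <- function(theta) {
  view <- cluster_view(theta)
  rate <- vapply(view, function(cl) abs(sum(cl$pi * diag(cl$R$R))), 0)
  rate / min(rate)
}

#' Train/test holdout splits
#'
#' The three split schemes used to compare models on held-out data:
#' \describe{
#'   \item{by_family}{families are partitioned at the given ratio; both parts
#'     keep the full species set and tree.}
#'   \item{by_species}{species are partitioned; each part gets the tree
#'     pruned to its species (pruning preserves path lengths between retained
#'     leaves) and the full family set.}
#'   \item{disjoint}{by_species, after which families present (nonzero) in
#'     both parts are randomly assigned exclusively to one part, so the
#'     train and test family sets are disjoint.}
#' }
#'
#' @param D species x families [ortholog_table()].
#' @param tree a [as_gcevo_tree()] tree.
#' @param mode one of \code{"by_family"}, \code{"by_species"},
#'   \code{"disjoint"}.
#' @param ratio train fraction in (0, 1); \code{0.8} gives the 4:1
#'   family split, \code{0.5} the 1:1 species split.
#' @param seed optional integer seed.
#' @return list with \code{train} and \code{test}, each a list of
#'   \code{table} and \code{tree}.
#' @export
split_holdout <- function(D, tree, mode = c("by_family", "by_species", "disjoint"),
                          ratio = 0.8, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) stop("'ratio' must be in (0,1)")
  if (!is.null(seed)) set.seed(seed)
  D <- align_table_tree(D, tree)
  if (mode == "by_family") {
    L <- ncol(D)
    n_train <- round(ratio * L)
    idx <- sort(sample.int(L, n_train))
    return(list(train = list(table = ortholog_table(unclass(D)[, idx, drop = FALSE]),
                             tree = tree),
                test = list(table = ortholog_table(unclass(D)[, -idx, drop = FALSE]),
                            tree = tree)))
  }
  sp <- rownames(D)
  n_train <- round(ratio * length(sp))
  if (n_train < 2L || length(sp) - n_train < 2L) {
    stop("each species subset must keep at least 2 leaves")
  }
  train_sp <- sort(sample.int(length(sp), n_train))
  parts <- list(train = sp[train_sp], test = sp[-train_sp])
  phy <- gcevo_tree_to_phylo(tree)
  out <- lapply(parts, function(keep) {
    pr <- ape::keep.tip(phy, keep)
    list(table = D[keep, , drop = FALSE], tree = as_gcevo_tree(pr))
  })
  if (mode == "disjoint") {
    shared <- which(colSums(out$train$table) > 0 & colSums(out$test$table) > 0)
    to_test <- shared[stats::runif(length(shared)) < 0.5]
    to_train <- setdiff(shared, to_test)
    drop_train <- c(to_test, which(colSums(out$train$table) == 0))
    drop_test <- c(to_train, which(colSums(out$test$table) == 0))
    out$train$table <- out$train$table[, setdiff(seq_len(ncol(D)), drop_train), drop = FALSE]
    out$test$table <- out$test$table[, setdiff(seq_len(ncol(D)), drop_test), drop = FALSE]
  }
  lapply(out, function(part) {
    part$table <- ortholog_table(unclass(part$table))
    part
  })
}
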