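# Shared fixtures: tiny trees and brute-force oracles used across tests.

# 3-leaf rooted binary tree ((A:.1,B:.2):.3,C:.4);
tree3 <- function() {
  as_gcevo_tree(ape::read.tree(text = "((A:0.1,B:0.2):0.3,C:0.4);"))
}

# 4-leaf balanced tree with assorted branch lengths
tree4 <- function(t = c(0.12, 0.34, 0.21, 0.08, 0.3, 0.17)) {
  txt <- sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g);",
                 t[1], t[2], t[5], t[3], t[4], t[6])
  as_gcevo_tree(ape::read.tree(text = txt))
}

# matrix exponential by truncated power series (independent oracle)
expm_series <- function(M, nterms = 60) {
  s <- nrow(M)
  out <- diag(s)
  term <- diag(s)
  for (n in seq_len(nterms)) {
    term <- term %*% M / n
    out <- out + term
  }
  out
}

# brute-force joint likelihood of a family on a gcevo_tree by enumerating all
# internal-node state assignments (independent oracle; small trees only)
enumerate_loglik <- function(D_l, R_k, pi_k, tree) {
  s <- R_k$lmax + 1L
  ints <- which(!tree$is_tip)
  P <- lapply(seq_len(tree$n_node - 1L), function(m) {
    expm_series(tree$brlen[m] * R_k$R)
  })
  tip_row <- cumsum(tree$is_tip)
  grid <- as.matrix(expand.grid(rep(list(0:(s - 1L)), length(ints))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(tree$n_node)
    st[ints] <- grid[g, ]
    st[tree$is_tip] <- D_l
    pr <- pi_k[st[tree$n_node] + 1L]
    for (m in seq_len(tree$n_node - 1L)) {
      pr <- pr * P[[m]][st[tree$parent[m]] + 1L, st[m] + 1L]
    }
    total <- total + pr
  }
  log(total)
}

# brute-force joint ancestral reconstruction by enumeration (oracle)
enumerate_viterbi <- function(D_l, R_k, pi_k, tree) {
  s <- R_k$lmax + 1L
  ints <- which(!tree$is_tip)
  P <- lapply(seq_len(tree$n_node - 1L), function(m) {
    expm_series(tree$brlen[m] * R_k$R)
  })
  grid <- as.matrix(expand.grid(rep(list(0:(s - 1L)), length(ints))))
  best <- -Inf
  best_st <- NULL
  for (g in seq_len(nrow(grid))) {
    st <- integer(tree$n_node)
    st[ints] <- grid[g, ]
    st[tree$is_tip] <- D_l
    pr <- log(pi_k[st[tree$n_node] + 1L])
    for (m in seq_len(tree$n_node - 1L)) {
      pr <- pr + log(P[[m]][st[tree$parent[m]] + 1L, st[m] + 1L])
    }
    if (pr > best + 1e-12) {
      best <- pr
      best_st <- st
    }
  }
  list(states = best_st, logscore = best)
}

# random mixture for property tests
random_theta <- function(kind = "bd", hetero = "pm", K = 2, lmax = 2) {
  random_init(kind, hetero, K, lmax)
}

# independent Gillespie path sampler on a raw generator matrix (states
# 0..lmax), recording dwell times and the transition-count matrix; used as a
# Monte-Carlo oracle for endpoint-conditioned moments. Deliberately does not
# reuse any package simulation code.
mc_path <- function(Rmat, a, t) {
  s <- nrow(Rmat)
  state <- a
  time <- 0
  dwell <- numeric(s)
  counts <- matrix(0, s, s)
  repeat {
    exit <- -Rmat[state + 1L, state + 1L]
    if (exit <= 0) {
      dwell[state + 1L] <- dwell[state + 1L] + (t - time)
      break
    }
    wait <- stats::rexp(1L, exit)
    if (time + wait >= t) {
      dwell[state + 1L] <- dwell[state + 1L] + (t - time)
      break
    }
    dwell[state + 1L] <- dwell[state + 1L] + wait
    time <- time + wait
    p <- Rmat[state + 1L, ]
    p[state + 1L] <- 0
    nxt <- sample.int(s, 1L, prob = p) - 1L
    counts[state + 1L, nxt + 1L] <- counts[state + 1L, nxt + 1L] + 1
    state <- nxt
  }
  list(end = state, dwell = dwell, counts = counts)
}

# Monte-Carlo endpoint-conditioned moments: simulate n paths from a, keep
# those ending in b, return mean dwell/counts with standard errors
mc_branch_moments <- function(Rmat, t, a, b, n) {
  s <- nrow(Rmat)
  dw <- matrix(NA_real_, n, s)
  ct <- array(NA_real_, c(n, s, s))
  acc <- 0L
  for (i in seq_len(n)) {
    p <- mc_path(Rmat, a, t)
    if (p$end == b) {
      acc <- acc + 1L
      dw[acc, ] <- p$dwell
      ct[acc, , ] <- p$counts
    }
  }
  dw <- dw[seq_len(acc), , drop = FALSE]
  ct <- ct[seq_len(acc), , , drop = FALSE]
  list(n = acc,
       dwell = colMeans(dw),
       dwell_se = apply(dw, 2L, stats::sd) / sqrt(acc),
       counts = apply(ct, c(2L, 3L), mean),
       counts_se = apply(ct, c(2L, 3L), stats::sd) / sqrt(acc))
}

# log joint score of a full state assignment (oracle scoring helper)
score_states <- function(st, R_k, pi_k, tree) {
  P <- lapply(seq_len(tree$n_node - 1L), function(m) {
    expm_series(tree$brlen[m] * R_k$R)
  })
  pr <- log(pi_k[st[tree$n_node] + 1L])
  for (m in seq_len(tree$n_node - 1L)) {
    pr <- pr + log(P[[m]][st[tree$parent[m]] + 1L, st[m] + 1L])
  }
  pr
}
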