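# EM engine: E-step by Felsenstein pruning + eigendecomposition integrals,
# M-step by exponential-family ratio maximizers (with small inner
# optimizations for the Csuros-Miklos gain law and the gamma shape).
#
# All per-family quantities are vectorized across families: inside/outside
# messages are (lmax+1) x L matrices per node, and the expected
# dwell-time/transition-count statistics of a whole branch are aggregated
# over families with three small matrix products per (cluster, branch).

# I_pq(t) = (exp(l_p t) - exp(l_q t)) / (l_p - l_q), with the t*exp(l_p t)
# limit for (near-)degenerate eigenvalue pairs
exp_integral_matrix <- function(values, t) {
  s <- length(values)
  el <- exp(values * t)
  den <- outer(values, values, "-")
  num <- outer(el, el, "-")
  close <- abs(den) < 1e-9 * pmax(1, abs(matrix(values, s, s)))
  I <- num / den
  I[close] <- matrix(t * el, s, s)[close]
  I
}

# per-cluster precomputation: eigensystem + transition matrix on every branch
cluster_branch_mats <- function(R_k, tree) {
  es <- rate_eigen(R_k)
  bn <- branch_nodes(tree)
  P <- vector("list", tree$n_node)
  for (m in bn) P[[m]] <- transition_matrix(es, tree$brlen[m])
  list(es = es, P = P)
}

# upward (inside) pass for one cluster, vectorized over families.
# D: species x families matrix aligned to tree tip order; states 0..lmax.
# Returns inside (list of s x L, column-scaled), msg (P_m %*% inside_m for
# every non-root node m), cumls (L-vector of cumulative log scalings at the
# root) and ll (per-family log-likelihood given root distribution pi).
inside_pass <- function(D, tree, P, pi, lmax) {
  s <- lmax + 1L
  L <- ncol(D)
  inside <- vector("list", tree$n_node)
  msg <- vector("list", tree$n_node)
  cumls <- vector("list", tree$n_node)
  tip_row <- cumsum(tree$is_tip)  # node index -> row of D
  for (m in seq_len(tree$n_node)) {
    if (tree$is_tip[m]) {
      states <- D[tip_row[m], ]
      ind <- matrix(0, s, L)
      ind[cbind(states + 1L, seq_len(L))] <- 1
      inside[[m]] <- ind
      cumls[[m]] <- numeric(L)
      msg[[m]] <- P[[m]][, states + 1L, drop = FALSE]
    } else {
      ch <- tree$children[m, ]
      raw <- msg[[ch[1L]]] * msg[[ch[2L]]]
      sc <- colSums(raw)
      inside[[m]] <- raw / rep(sc, each = s)
      cumls[[m]] <- cumls[[ch[1L]]] + cumls[[ch[2L]]] + log(sc)
      if (m < tree$n_node) msg[[m]] <- P[[m]] %*% inside[[m]]
    }
  }
  root <- tree_root(tree)
  ll <- log(colSums(pi * inside[[root]])) + cumls[[root]]
  list(inside = inside, msg = msg, cumls = cumls[[root]], ll = ll)
}

#' Pruning likelihood of a single gene family
#'
#' Computes the inside (conditional likelihood) vectors of Felsenstein's
#' pruning algorithm for one family under one cluster's generator and root
#' distribution, with per-node scaling so large trees do not underflow.
#'
#' @param D_l integer vector of leaf copy numbers, in the tree's leaf order
#'   (or named by species).
#' @param R_k a [build_rate_matrix()] generator.
#' @param pi_k root distribution over states 0..lmax.
#' @param tree a [as_gcevo_tree()] tree.
#' @return list with \code{inside} ((lmax+1) x n_node matrix of column-scaled
#'   inside vectors), \code{log_scale} (summed log scaling constants) and
#'   \code{loglik}.
#' @export
family_inside <- function(D_l, R_k, pi_k, tree) {
  if (!is.null(names(D_l))) D_l <- D_l[tip_labels(tree)]
  if (length(D_l) != tree$n_tip || anyNA(D_l)) {
    stop("D_l must give one state per tree leaf")
  }
  if (any(D_l < 0 | D_l > R_k$lmax)) stop("leaf states must lie in 0..lmax")
  cb <- cluster_branch_mats(R_k, tree)
  ip <- inside_pass(matrix(as.integer(D_l), ncol = 1L), tree, cb$P,
                    pi_k, R_k$lmax)
  list(inside = do.call(cbind, lapply(ip$inside, drop)),
       log_scale = ip$cumls, loglik = ip$ll)
}

# kernel-ready description of the tree and mixture
kernel_tree <- function(tree) {
  parent <- tree$parent; parent[is.na(parent)] <- 0L
  children <- tree$children; children[is.na(children)] <- 0L
  tip_row <- cumsum(tree$is_tip); tip_row[!tree$is_tip] <- 0L
  brlen <- tree$brlen; brlen[is.na(brlen)] <- 0
  list(parent = parent, children = children, tip_row = as.integer(tip_row),
       brlen = brlen)
}

kernel_clusters <- function(theta) {
  lapply(cluster_view(theta), function(cl) {
    es <- rate_eigen(cl$R)
    list(values = es$values, U = es$U, Uinv = es$Uinv, R = es$R, pi = cl$pi)
  })
}

# log-likelihood matrix (families x clusters) for a parameter set
cluster_logliks <- function(theta, D, tree) {
  kt <- kernel_tree(tree)
  Dm <- matrix(as.integer(D), nrow = nrow(D))
  .em_estep_kernel(Dm, kt$parent, kt$children, kt$tip_row, kt$brlen,
                   kernel_clusters(theta), theta$phi,
                   rep(1, ncol(D)), FALSE)$ll
}

#' Posterior cluster responsibilities
#'
#' For every family, the posterior probability that it belongs to each
#' cluster: \code{gamma_lk = phi_k p(D_l | R_k, pi_k) / sum_j phi_j p(D_l |
#' R_j, pi_j)}, computed in log space.
#'
#' @param theta a [mixture_params()] object.
#' @param D species x families copy-number matrix aligned to the tree.
#' @param tree a [as_gcevo_tree()] tree.
#' @return L x K matrix with rows on the simplex.
#' @export
responsibilities <- function(theta, D, tree) {
  ll <- cluster_logliks(theta, D, tree)
  log_post <- ll + rep(log(theta$phi), each = nrow(ll))
  mx <- apply(log_post, 1L, max)
  g <- exp(log_post - mx)
  g / rowSums(g)
}

#' Held-out log-likelihood
#'
#' Mixture log-likelihood of a test table under fixed, already-estimated
#' parameters (no updates). Copy numbers above the model's lmax are clipped.
#'
#' @inheritParams responsibilities
#' @param D_test species x families copy-number table whose species set
#'   equals the tree's leaves.
#' @return scalar log-likelihood.
#' @export
heldout_loglik <- function(theta, D_test, tree) {
  D_test <- align_table_tree(D_test, tree)
  D_test <- suppressMessages(clip_copy_numbers(D_test, theta$lmax))
  ll <- cluster_logliks(theta, unclass(D_test), tree)
  log_mix <- ll + rep(log(theta$phi), each = nrow(ll))
  mx <- apply(log_mix, 1L, max)
  sum(mx + log(rowSums(exp(log_mix - mx))))
}

#' Joint posterior of a branch's endpoint states
#'
#' For a single family and cluster, the posterior distribution of the
#' (parent state, child state) pair across one branch given the leaf data:
#' \code{p(a, b)} proportional to \code{outside_parent(a) P(b|a,t)
#' inside_child(b)}.
#'
#' @inheritParams family_inside
#' @param node index of the non-root node under the branch.
#' @return (lmax+1) x (lmax+1) matrix summing to one, rows = parent state.
#' @export
branch_joint_posterior <- function(D_l, R_k, pi_k, tree, node) {
  if (node >= tree_root(tree)) stop("'node' must be a non-root node")
  if (!is.null(names(D_l))) D_l <- D_l[tip_labels(tree)]
  Dm <- matrix(as.integer(D_l), ncol = 1L)
  cb <- cluster_branch_mats(R_k, tree)
  ip <- inside_pass(Dm, tree, cb$P, pi_k, R_k$lmax)
  out <- outside_pass(tree, cb$P, pi_k, ip, lmax = R_k$lmax)
  p <- tree$parent[node]
  joint <- (out[[p]][, 1L] %o% rep(1, R_k$lmax + 1L)) * cb$P[[node]] *
    rep(ip$inside[[node]][, 1L], each = R_k$lmax + 1L)
  joint / sum(joint)
}

# downward (outside) pass; out[[m]] columns are proportional to
# p(data above m, state at m) per family (column-normalized)
outside_pass <- function(tree, P, pi, ip, lmax) {
  s <- lmax + 1L
  L <- ncol(ip$inside[[1L]])
  out <- vector("list", tree$n_node)
  root <- tree_root(tree)
  out[[root]] <- matrix(pi, s, L)
  for (p in rev(internal_nodes(tree))) {
    ch <- tree$children[p, ]
    for (j in 1:2) {
      c1 <- ch[j]; sib <- ch[3L - j]
      o <- crossprod(P[[c1]], out[[p]] * ip$msg[[sib]])
      out[[c1]] <- o / rep(colSums(o), each = s)
    }
  }
  out
}

#' Endpoint-conditioned dwell times and transition counts
#'
#' Expected time spent in each state and expected number of each +-1
#' transition on a branch of length \code{t}, conditional on the chain
#' starting in state \code{a} and ending in state \code{b}, computed from the
#' generator's eigensystem via the two-exponential integrals
#' \code{I_pq(t) = (exp(l_p t) - exp(l_q t)) / (l_p - l_q)}.
#'
#' @param R_k a [build_rate_matrix()] generator.
#' @param t branch length (> 0).
#' @param a,b start and end copy-number states (0..lmax).
#' @return list with \code{dwell} (expected time per state, sums to \code{t})
#'   and \code{counts} ((lmax+1)^2 matrix of expected transition counts, zero
#'   off the tridiagonal).
#' @export
endpoint_conditioned_moments <- function(R_k, t, a, b) {
  es <- rate_eigen(R_k)
  s <- R_k$lmax + 1L
  P <- transition_matrix(es, t)
  pab <- P[a + 1L, b + 1L]
  if (pab < 1e-300) {
    stop("transition probability from ", a, " to ", b, " in time ", t,
         " is numerically zero")
  }
  I <- exp_integral_matrix(es$values, t)
  J <- (es$U[a + 1L, ] %o% es$Uinv[, b + 1L]) * I
  G <- t(es$Uinv) %*% J %*% t(es$U)
  dwell <- pmax(diag(G), 0) / pab
  counts <- es$R * G / pab
  diag(counts) <- 0
  counts[counts < 0] <- 0
  list(dwell = dwell, counts = counts)
}

#' E-step: responsibilities and expected sufficient statistics
#'
#' One expectation step of the EM algorithm: computes posterior cluster
#' responsibilities and, for every cluster and branch, the expected time
#' spent in each state and the expected number of each +-1 transition,
#' aggregated over families with responsibility weights, plus expected
#' root-state counts.
#'
#' @inheritParams responsibilities
#' @param weights optional per-family multiplicities (used internally to
#'   collapse duplicate copy-number patterns).
#' @return list with \code{gamma} (L x K), \code{loglik} (total observed-data
#'   log-likelihood), \code{family_loglik}, and \code{stats}: per cluster,
#'   \code{dwell} (branch x state expected dwell times), \code{counts}
#'   (state x state x branch expected transition counts), their totals
#'   \code{T} (state vector) and \code{N} (state x state), \code{n_root}
#'   (K x state) and \code{gamma_total} (summed responsibilities per
#'   cluster).
#' @export
e_step <- function(theta, D, tree, weights = NULL) {
  stopifnot(inherits(theta, "mixture_params"))
  if (is.null(weights)) weights <- rep(1, ncol(D))
  kt <- kernel_tree(tree)
  Dm <- matrix(as.integer(D), nrow = nrow(D))
  res <- .em_estep_kernel(Dm, kt$parent, kt$children, kt$tip_row, kt$brlen,
                          kernel_clusters(theta), theta$phi, weights, TRUE)
  list(gamma = res$gamma, loglik = res$loglik,
       family_loglik = as.numeric(res$family_loglik),
       stats = lapply(res$stats, function(st) {
         list(dwell = st$dwell, counts = st$counts,
              T = as.numeric(st$T), N = st$N,
              gamma_total = st$gamma_total)
       }),
       n_root = res$n_root)
}

# reference implementation of the E-step in plain R; used to cross-check the
# compiled kernel on small instances
e_step_r <- function(theta, D, tree, weights = NULL) {
  stopifnot(inherits(theta, "mixture_params"))
  s <- theta$lmax + 1L
  L <- ncol(D)
  if (is.null(weights)) weights <- rep(1, L)
  view <- cluster_view(theta)
  K <- theta$K
  root <- tree_root(tree)
  bn <- branch_nodes(tree)

  cbs <- vector("list", K)
  ips <- vector("list", K)
  ll <- matrix(0, L, K)
  for (k in seq_len(K)) {
    cbs[[k]] <- cluster_branch_mats(view[[k]]$R, tree)
    ips[[k]] <- inside_pass(D, tree, cbs[[k]]$P, view[[k]]$pi, theta$lmax)
    ll[, k] <- ips[[k]]$ll
  }
  log_post <- ll + rep(log(theta$phi), each = L)
  mx <- apply(log_post, 1L, max)
  ex <- exp(log_post - mx)
  gamma <- ex / rowSums(ex)
  family_loglik <- mx + log(rowSums(ex))
  loglik <- sum(weights * family_loglik)

  n_root <- matrix(0, K, s)
  stats <- vector("list", K)
  for (k in seq_len(K)) {
    es <- cbs[[k]]$es
    P <- cbs[[k]]$P
    ip <- ips[[k]]
    gw <- gamma[, k] * weights
    out <- outside_pass(tree, P, view[[k]]$pi, ip, theta$lmax)
    # root-state expectations
    rpost <- view[[k]]$pi * ip$inside[[root]]
    rpost <- rpost / rep(colSums(rpost), each = s)
    n_root[k, ] <- as.numeric(rpost %*% gw)
    dwell <- matrix(0, tree$n_node, s)
    counts <- array(0, c(s, s, tree$n_node))
    tU <- t(es$U); tUinv <- t(es$Uinv)
    for (m in bn) {
      p <- tree$parent[m]
      norm <- colSums(out[[p]] * ip$msg[[m]])
      w <- gw / norm
      X <- crossprod(es$U, out[[p]])          # s x L
      Y <- es$Uinv %*% ip$inside[[m]]         # s x L
      J <- (X * rep(w, each = s)) %*% t(Y)
      J <- J * exp_integral_matrix(es$values, tree$brlen[m])
      M <- tUinv %*% J %*% tU
      dwell[m, ] <- pmax(diag(M), 0)
      cnt <- es$R * M
      diag(cnt) <- 0
      cnt[cnt < 0] <- 0
      counts[, , m] <- cnt
    }
    stats[[k]] <- list(dwell = dwell, counts = counts,
                       T = colSums(dwell),
                       N = apply(counts, c(1L, 2L), sum),
                       gamma_total = sum(gw))
  }
  list(gamma = gamma, loglik = loglik, family_loglik = family_loglik,
       stats = stats, n_root = n_root)
}

# --- M-step -----------------------------------------------------------------

RATE_CAP <- 1e6

# closed-form / concave-optimization rate updates given pooled expected
# transition counts N (s x s) and effective dwell times T (length s)
rate_mstep <- function(kind, N, T, lmax) {
  s <- lmax + 1L
  gi <- cbind(1:lmax, 2:s)       # gain cells, states 0..lmax-1
  li <- cbind(2:s, 1:lmax)       # loss cells, states 1..lmax
  safe_ratio <- function(n, t) {
    if (t <= 0) {
      if (n > 0) {
        warning("zero expected dwell time with nonzero transition counts; rate capped")
        return(RATE_CAP)
      }
      return(RATE_FLOOR)
    }
    max(min(n / t, RATE_CAP), RATE_FLOOR)
  }
  if (kind == "bd") {
    list(alpha = safe_ratio(sum(N[gi]), sum(T[1:lmax])),
         beta = safe_ratio(sum(N[li]), sum(T[2:s])))
  } else if (kind == "bdi") {
    delta <- safe_ratio(N[1L, 2L], T[1L])
    alpha <- if (lmax >= 2L) {
      safe_ratio(sum(N[gi][-1L]), sum(T[2:lmax]))
    } else delta
    list(delta = delta, alpha = alpha, beta = safe_ratio(sum(N[li]), sum(T[2:s])))
  } else if (kind == "bdard") {
    list(gain = vapply(seq_len(lmax), function(i) safe_ratio(N[gi[i, 1L], gi[i, 2L]], T[i]), 0),
         loss = vapply(seq_len(lmax), function(i) safe_ratio(N[li[i, 1L], li[i, 2L]], T[i + 1L]), 0))
  } else if (kind == "cm") {
    beta <- safe_ratio(sum(N[li]), sum((1:lmax) * T[2:s]))
    ng <- N[gi]                   # gain counts out of states 0..lmax-1
    tg <- T[1:lmax]
    i0 <- 0:(lmax - 1L)
    # maximize sum_i ng_i log(alpha + i*gamma) - (alpha + i*gamma) tg_i,
    # concave in (alpha, gamma) on the positive orthant
    negq <- function(p) {
      r <- p[1L] + i0 * p[2L]
      -sum(ng * log(r) - r * tg)
    }
    grad <- function(p) {
      r <- p[1L] + i0 * p[2L]
      -c(sum(ng / r - tg), sum(i0 * (ng / r - tg)))
    }
    start <- c(max(sum(ng) / max(sum(tg), 1e-12), RATE_FLOOR), RATE_FLOOR * 10)
    opt <- stats::optim(start, negq, grad, method = "L-BFGS-B",
                        lower = c(RATE_FLOOR, RATE_FLOOR),
                        upper = c(RATE_CAP, RATE_CAP))
    list(alpha = opt$par[1L], beta = beta, gamma = opt$par[2L])
  } else stop("unknown kind")
}

# exit rate per state of a generator (sum of off-diagonal row entries)
exit_rates <- function(rm) -diag(rm$R)

m_step <- function(estep, theta) {
  K <- theta$K
  lmax <- theta$lmax
  s <- lmax + 1L
  gt <- vapply(estep$stats, `[[`, 0, "gamma_total")
  Lw <- sum(gt)
  phi <- gt / Lw
  if (theta$hetero == "pm") {
    pi <- estep$n_root / rowSums(estep$n_root)
    rates <- lapply(seq_len(K), function(k) {
      build_rate_matrix(theta$kind,
                        rate_mstep(theta$kind, estep$stats[[k]]$N,
                                   estep$stats[[k]]$T, lmax),
                        lmax)
    })
    return(mixture_params(theta$kind, "pm", K, lmax, phi = phi,
                          rates = rates, pi = pi))
  }
  # shared-matrix models: coordinate ascent between base R and multipliers
  pi <- colSums(estep$n_root)
  pi <- pi / sum(pi)
  Nk <- lapply(estep$stats, `[[`, "N")
  Tk <- do.call(rbind, lapply(estep$stats, `[[`, "T"))  # K x s dwell times
  Npool <- Reduce(`+`, Nk)
  totN <- vapply(Nk, sum, 0)
  r <- theta$r
  base <- theta$rates[[1L]]
  shape <- theta$gamma_shape
  for (sweep in 1:2) {
    Teff <- as.numeric(crossprod(Tk, r))   # sum_k r_k T_k(i)
    base <- build_rate_matrix(theta$kind,
                              rate_mstep(theta$kind, Npool, Teff, lmax), lmax)
    ex <- exit_rates(base)
    B <- as.numeric(Tk %*% ex)             # sum_i exit_i(R) T_k(i)
    if (theta$hetero == "pdf") {
      r <- pmax(totN, 1e-12) / pmax(B, 1e-12)
    } else {
      obj <- function(la) {
        rk <- gamma_category_rates(exp(la), K)
        sum(totN * log(rk) - rk * B)
      }
      opt <- stats::optimize(obj, interval = log(c(0.01, 100)), maximum = TRUE)
      shape <- exp(opt$maximum)
      r <- gamma_category_rates(shape, K)
    }
  }
  if (theta$hetero == "pdf") {
    mixture_params(theta$kind, "pdf", K, lmax, phi = phi, rates = base,
                   pi = pi, r = r)
  } else {
    mixture_params(theta$kind, "gamma", K, lmax, rates = base, pi = pi,
                   gamma_shape = shape)
  }
}

# order clusters by decreasing mixing probability (r for the gamma model,
# whose phi are tied); the labeling is otherwise unidentifiable
canonicalize_clusters <- function(theta) {
  if (theta$hetero == "gamma") return(theta)  # r_k already ordered
  ord <- order(theta$phi, decreasing = TRUE)
  theta$phi <- theta$phi[ord]
  if (theta$hetero == "pm") {
    theta$rates <- theta$rates[ord]
    theta$pi <- theta$pi[ord, , drop = FALSE]
  } else {
    theta$r <- theta$r[ord]
  }
  theta
}

#' Fit a gene-content evolution mixture model
#'
#' Maximum-likelihood estimation of a gain/loss mixture model from an
#' ortholog table and a rooted binary species tree by the EM algorithm with
#' random restarts. Each restart starts from [random_init()] parameters and
#' alternates [e_step()] and the M-step until the relative change in
#' log-likelihood drops below \code{tol}; the restart with the largest final
#' log-likelihood is returned. Identical duplicate copy-number patterns are
#' collapsed internally (with multiplicity weights), which changes nothing
#' mathematically but speeds up large tables.
#'
#' @param D species x families [ortholog_table()] (copy numbers above
#'   \code{lmax} are clipped with a message).
#' @param tree a [as_gcevo_tree()] tree whose leaves match the table species.
#' @param kind gain/loss model kind (see [build_rate_matrix()]).
#' @param hetero heterogeneity kind (see [mixture_params()]).
#' @param K number of clusters.
#' @param lmax copy-number truncation bound.
#' @param restarts number of random EM restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param seed integer seed making the whole fit reproducible.
#' @param verbose print per-restart progress.
#' @return an object of class \code{gcevo_fit}: list with \code{theta} (the
#'   winning [mixture_params()], clusters ordered by decreasing phi),
#'   \code{loglik}, \code{gamma} (responsibilities under \code{theta}),
#'   \code{trace} (winning restart's log-likelihood path),
#'   \code{restart_logliks}, \code{restart} (winner index),
#'   \code{iterations} and \code{converged}.
#' @export
fit_gene_content <- function(D, tree, kind = c("bd", "cm", "bdi", "bdard"),
                             hetero = c("pm", "pdf", "gamma"), K, lmax,
                             restarts = 100L, tol = 1e-7, max_iter = 1000L,
                             seed = NULL, verbose = FALSE) {
  kind <- match.arg(kind)
  hetero <- match.arg(hetero)
  if (restarts < 1L) stop("restarts must be >= 1")
  D <- align_table_tree(D, tree)
  D <- clip_copy_numbers(D, lmax)
  if (max(D) < lmax) {
    warning("lmax exceeds the largest observed copy number; rates of ",
            "unobservable transitions will sit at the floor")
  }
  Dm <- unclass(D)
  # collapse duplicate copy-number patterns
  key <- apply(Dm, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pattern_of <- match(key, key[first])
  Du <- Dm[, first, drop = FALSE]
  w <- as.numeric(table(factor(pattern_of, levels = seq_len(sum(first)))))

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  restart_ll <- rep(NA_real_, restarts)
  for (rs in seq_len(restarts)) {
    theta <- random_init(kind, hetero, K, lmax)
    trace <- numeric(0)
    converged <- FALSE
    res <- NULL
    for (it in seq_len(max_iter)) {
      res <- tryCatch(e_step(theta, Du, tree, weights = w),
                      error = function(e) e)
      if (inherits(res, "error")) break
      trace <- c(trace, res$loglik)
      if (it > 1L &&
          abs(trace[it] - trace[it - 1L]) < tol * abs(trace[it])) {
        converged <- TRUE
        break
      }
      theta <- m_step(res, theta)
    }
    if (inherits(res, "error") || is.null(res)) {
      if (verbose) message("restart ", rs, " failed: ", conditionMessage(res))
      next
    }
    restart_ll[rs] <- trace[length(trace)]
    if (verbose) {
      message(sprintf("restart %d: loglik %.4f after %d iterations%s",
                      rs, restart_ll[rs], length(trace),
                      if (converged) "" else " (max_iter reached)"))
    }
    if (is.null(best) || restart_ll[rs] > best$loglik) {
      best <- list(theta = theta, loglik = restart_ll[rs], trace = trace,
                   restart = rs, iterations = length(trace),
                   converged = converged)
    }
  }
  if (is.null(best)) stop("all EM restarts failed numerically")
  theta <- canonicalize_clusters(best$theta)
  gamma <- responsibilities(theta, Dm, tree)
  rownames(gamma) <- colnames(D)
  structure(list(theta = theta, loglik = best$loglik, gamma = gamma,
                 trace = best$trace, restart_logliks = restart_ll,
                 restart = best$restart, iterations = best$iterations,
                 converged = best$converged,
                 n_families = ncol(D), n_species = nrow(D)),
            class = "gcevo_fit")
}

#' @export
print.gcevo_fit <- function(x, ...) {
  cat("gcevo_fit: ", toupper(x$theta$kind), " + ", toupper(x$theta$hetero),
      ", K = ", x$theta$K, ", lmax = ", x$theta$lmax, "\n", sep = "")
  cat(sprintf("log-likelihood %.4f (restart %d, %d iterations, %s)\n",
              x$loglik, x$restart, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(x$n_families, "families,", x$n_species, "species\n")
  invisible(x)
}

#' @export
logLik.gcevo_fit <- function(object, ...) {
  structure(object$loglik, class = "logLik",
            nobs = object$n_families)
}
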