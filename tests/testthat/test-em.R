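# em_engine: pruning likelihoods, expected sufficient statistics, M-step, EM

test_that("pruning log-likelihood matches brute-force enumeration", {
  set.seed(31)
  for (tr in list(tree3(), tree4())) {
    for (kind in c("bd", "cm", "bdard")) {
      rm <- random_rate_matrix(kind, 2L)
      pi <- rdirichlet1(3L)
      for (rep in 1:3) {
        D_l <- sample(0:2, tr$n_tip, replace = TRUE)
        fi <- family_inside(D_l, rm, pi, tr)
        expect_equal(fi$loglik, enumerate_loglik(D_l, rm, pi, tr),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("mixture held-out log-likelihood matches enumeration", {
  set.seed(32)
  tr <- tree4()
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  m <- matrix(sample(0:2, 12, replace = TRUE), 4, 3,
              dimnames = list(tip_labels(tr), paste0("f", 1:3)))
  D <- ortholog_table(m)
  view <- cluster_view(theta)
  oracle <- sum(vapply(1:3, function(l) {
    liks <- vapply(1:2, function(k) {
      exp(enumerate_loglik(m[, l], view[[k]]$R, view[[k]]$pi, tr))
    }, 0)
    log(sum(theta$phi * liks))
  }, 0))
  expect_equal(heldout_loglik(theta, D, tr), oracle, tolerance = 1e-8)
})

test_that("responsibilities are posterior cluster probabilities", {
  set.seed(33)
  tr <- tree3()
  theta <- random_theta("bdard", "pm", K = 3L, lmax = 2L)
  D <- matrix(sample(0:2, 6, replace = TRUE), 3, 2,
              dimnames = list(tip_labels(tr), c("f1", "f2")))
  g <- responsibilities(theta, D, tr)
  expect_equal(unname(rowSums(g)), c(1, 1), tolerance = 1e-12)
  view <- cluster_view(theta)
  for (l in 1:2) {
    post <- theta$phi * vapply(1:3, function(k) {
      exp(enumerate_loglik(D[, l], view[[k]]$R, view[[k]]$pi, tr))
    }, 0)
    expect_equal(g[l, ], post / sum(post), tolerance = 1e-8)
  }
})

test_that("branch joint posterior is a distribution consistent with pruning", {
  set.seed(34)
  tr <- tree4()
  rm <- random_rate_matrix("bd", 2L)
  pi <- rdirichlet1(3L)
  D_l <- c(2L, 0L, 1L, 0L)
  for (node in c(1L, 5L)) {
    J <- branch_joint_posterior(D_l, rm, pi, tr, node)
    expect_equal(sum(J), 1, tolerance = 1e-10)
    expect_true(all(J >= 0))
  }
  expect_error(branch_joint_posterior(D_l, rm, pi, tr, tree_root(tr)))
})

test_that("endpoint-conditioned dwell times sum to the branch length", {
  set.seed(35)
  rm <- random_rate_matrix("bdard", 3L)
  for (t in c(0.05, 0.6, 3)) {
    for (ab in list(c(0, 0), c(0, 3), c(2, 1))) {
      mom <- endpoint_conditioned_moments(rm, t, ab[1L], ab[2L])
      expect_equal(sum(mom$dwell), t, tolerance = 1e-8)
      expect_true(all(mom$dwell >= 0))
      expect_true(all(mom$counts >= 0))
      # counts live on the tridiagonal only
      off <- mom$counts
      off[cbind(1:3, 2:4)] <- 0
      off[cbind(2:4, 1:3)] <- 0
      expect_equal(max(abs(off)), 0)
    }
  }
})

test_that("endpoint-conditioned moments match a Monte-Carlo oracle", {
  set.seed(36)
  rm <- build_rate_matrix("bd", list(alpha = 0.9, beta = 1.2), 2L)
  t <- 0.8; a <- 1L; b <- 0L
  mc <- mc_branch_moments(rm$R, t, a, b, n = 30000L)
  expect_gt(mc$n, 2000L)   # enough accepted paths for tight standard errors
  mom <- endpoint_conditioned_moments(rm, t, a, b)
  for (i in 1:3) {
    expect_lt(abs(mom$dwell[i] - mc$dwell[i]), 4 * mc$dwell_se[i] + 1e-4)
  }
  cells <- rbind(c(1, 2), c(2, 3), c(2, 1), c(3, 2))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1L]; j <- cells[r, 2L]
    expect_lt(abs(mom$counts[i, j] - mc$counts[i, j]),
              4 * mc$counts_se[i, j] + 1e-4)
  }
})

test_that("compiled E-step kernel agrees with the plain-R reference", {
  set.seed(37)
  tr <- as_gcevo_tree(ape::rcoal(10))
  for (spec in list(c("bd", "pm"), c("bdard", "pm"), c("cm", "pdf"),
                    c("bd", "gamma"))) {
    theta <- random_theta(spec[1L], spec[2L], K = 3L, lmax = 3L)
    D <- matrix(sample(0:3, 10 * 25, replace = TRUE, prob = c(4, 3, 2, 1)),
                10, 25)
    w <- sample(1:3, 25, replace = TRUE)
    a <- e_step(theta, D, tr, weights = w)
    b <- e_step_r(theta, D, tr, weights = w)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-10)
    expect_equal(a$gamma, b$gamma, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(a$n_root, b$n_root, tolerance = 1e-8, ignore_attr = TRUE)
    for (k in 1:3) {
      expect_equal(a$stats[[k]]$T, b$stats[[k]]$T, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(a$stats[[k]]$N, b$stats[[k]]$N, tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(a$stats[[k]]$gamma_total, b$stats[[k]]$gamma_total,
                   tolerance = 1e-7)
    }
  }
})

test_that("expected dwell times conserve weighted branch lengths", {
  set.seed(38)
  tr <- tree4()
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  D <- matrix(sample(0:2, 4 * 30, replace = TRUE), 4, 30)
  es <- e_step(theta, D, tr)
  for (k in 1:2) {
    gw_total <- sum(es$gamma[, k])
    dwell <- es$stats[[k]]$dwell
    for (m in branch_nodes(tr)) {
      expect_equal(sum(dwell[m, ]), tr$brlen[m] * gw_total, tolerance = 1e-8)
    }
    # total expected root-state mass equals total responsibility
    expect_equal(sum(es$n_root[k, ]), gw_total, tolerance = 1e-8)
  }
})

test_that("BD M-step is the expected-count / expected-dwell ratio", {
  N <- matrix(0, 3, 3)
  N[1, 2] <- 4; N[2, 3] <- 2; N[2, 1] <- 5; N[3, 2] <- 1
  T <- c(10, 6, 2)
  p <- rate_mstep("bd", N, T, 2L)
  expect_equal(p$alpha, (4 + 2) / (10 + 6))
  expect_equal(p$beta, (5 + 1) / (6 + 2))
  pa <- rate_mstep("bdard", N, T, 2L)
  expect_equal(pa$gain, c(4 / 10, 2 / 6))
  expect_equal(pa$loss, c(5 / 6, 1 / 2))
  pi_ <- rate_mstep("bdi", N, T, 2L)
  expect_equal(pi_$delta, 4 / 10)
  expect_equal(pi_$alpha, 2 / 6)
})

test_that("C&M M-step maximizes its expected complete-data objective", {
  N <- matrix(0, 4, 4)
  N[cbind(1:3, 2:4)] <- c(6, 9, 5)
  N[cbind(2:4, 1:3)] <- c(7, 8, 3)
  T <- c(12, 9, 4, 2)
  p <- rate_mstep("cm", N, T, 3L)
  q <- function(alpha, gam) {
    r <- alpha + (0:2) * gam
    sum(N[cbind(1:3, 2:4)] * log(r) - r * T[1:3])
  }
  base <- q(p$alpha, p$gamma)
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    a2 <- p$alpha + d[1L]; g2 <- p$gamma + d[2L]
    if (a2 > 0 && g2 > 0) expect_lte(q(a2, g2), base + 1e-9)
  }
  expect_equal(p$beta, (7 + 8 + 3) / sum((1:3) * T[2:4]))
})

test_that("zero dwell with nonzero counts caps the rate with a warning", {
  N <- matrix(0, 2, 2); N[1, 2] <- 3
  expect_warning(p <- rate_mstep("bd", N, c(0, 1), 1L), "capped")
  expect_equal(p$alpha, 1e6)
})

test_that("EM iterations never decrease the log-likelihood", {
  set.seed(39)
  tr <- as_gcevo_tree(ape::rcoal(8))
  theta0 <- random_theta("bd", "pm", K = 2L, lmax = 3L)
  sim <- simulate_dataset(theta0, tr, L = 80L)
  D <- unclass(sim$table)
  for (spec in list(c("bd", "pm"), c("cm", "pdf"), c("bd", "gamma"),
                    c("bdi", "pm"))) {
    theta <- random_init(spec[1L], spec[2L], K = 2L, lmax = 3L)
    ll <- numeric(0)
    for (it in 1:15) {
      es <- e_step(theta, D, tr)
      ll <- c(ll, es$loglik)
      theta <- m_step(es, theta)
    }
    expect_true(all(diff(ll) > -1e-7 * abs(ll[-1L])),
                info = paste(spec, collapse = "+"))
  }
})

test_that("fit_gene_content is reproducible and returns a coherent fit", {
  set.seed(40)
  tr <- as_gcevo_tree(ape::rcoal(8))
  theta0 <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  sim <- simulate_dataset(theta0, tr, L = 60L, seed = 401L)
  f1 <- fit_gene_content(sim$table, tr, "bd", "pm", K = 2L, lmax = 2L,
                         restarts = 3L, seed = 77L)
  f2 <- fit_gene_content(sim$table, tr, "bd", "pm", K = 2L, lmax = 2L,
                         restarts = 3L, seed = 77L)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
  expect_equal(f1$theta$phi, f2$theta$phi, tolerance = 1e-12)
  # clusters come back in canonical order
  expect_true(all(diff(f1$theta$phi) <= 1e-12))
  # winner really is the best restart
  expect_equal(f1$loglik, max(f1$restart_logliks, na.rm = TRUE))
  # responsibilities match an independent recomputation under theta-hat
  g <- responsibilities(f1$theta, unclass(align_table_tree(sim$table, tr)), tr)
  expect_equal(unname(f1$gamma), unname(g), tolerance = 1e-10)
  expect_equal(attr(logLik(f1), "nobs"), 60L)
})

test_that("EM recovers generating parameters from a large simulated table", {
  # moderate-size recovery study: two well-separated BD clusters
  set.seed(411)
  tr <- yule_branch_lengths(perfect_binary_tree(64L), 5.0)
  theta0 <- mixture_params(
    "bd", "pm", K = 2L, lmax = 3L, phi = c(0.6, 0.4),
    rates = list(build_rate_matrix("bd", list(alpha = 0.4, beta = 0.6), 3L),
                 build_rate_matrix("bd", list(alpha = 1.4, beta = 1.1), 3L)),
    pi = rbind(c(0.4, 0.3, 0.2, 0.1), c(0.1, 0.2, 0.3, 0.4)))
  sim <- simulate_dataset(theta0, tr, L = 2000L, seed = 412L)
  fit <- fit_gene_content(sim$table, tr, "bd", "pm", K = 2L, lmax = 3L,
                          restarts = 4L, seed = 413L)
  p <- match_clusters(fit$theta, theta0)
  vh <- cluster_view(fit$theta)[p]
  vt <- cluster_view(theta0)
  for (k in 1:2) {
    rh <- c(rate_gains(vh[[k]]$R), rate_losses(vh[[k]]$R))
    rt <- c(rate_gains(vt[[k]]$R), rate_losses(vt[[k]]$R))
    expect_lt(max(abs(rh - rt) / rt), 0.25)
    expect_lt(max(abs(vh[[k]]$pi - vt[[k]]$pi)), 0.1)
  }
  expect_lt(max(abs(fit$theta$phi[p] - theta0$phi)), 0.1)
})
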