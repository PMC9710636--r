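# evaluation: cluster matching, relative errors, accuracy metrics, holdouts

test_that("match_clusters undoes a known label permutation", {
  set.seed(71)
  theta <- random_theta("bdard", "pm", K = 3L, lmax = 2L)
  perm <- c(3L, 1L, 2L)
  shuffled <- mixture_params("bdard", "pm", K = 3L, lmax = 2L,
                             phi = theta$phi[perm],
                             rates = theta$rates[perm],
                             pi = theta$pi[perm, , drop = FALSE])
  p <- match_clusters(shuffled, theta)
  # cluster p[k] of 'shuffled' must be cluster k of 'theta'
  expect_equal(perm[p], 1:3)
})

test_that("relative errors are zero for identical parameters and exact for known shifts", {
  set.seed(72)
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  re <- relative_errors(theta, theta)
  expect_true(all(abs(unlist(re$errors)) < 1e-10))
  expect_true(all(re$iqr >= 0))
  # scale every rate of every cluster by 1.1: all R errors exactly +10
  scaled <- theta
  scaled$rates <- lapply(theta$rates, scale_rate_matrix, c = 1.1)
  re2 <- relative_errors(scaled, theta)
  expect_equal(unname(re2$errors$R), rep(10, length(re2$errors$R)),
               tolerance = 1e-8)
  expect_equal(unname(re2$iqr["R"]), 0, tolerance = 1e-8)
})

test_that("relative errors warn on and exclude zero-valued true parameters", {
  base <- build_rate_matrix("bd", list(alpha = 1, beta = 1), 1L)
  mk <- function(pi1) {
    mixture_params("bd", "pm", K = 1L, lmax = 1L, phi = 1,
                   rates = list(base), pi = matrix(pi1, 1L))
  }
  expect_warning(re <- relative_errors(mk(c(0.5, 0.5)), mk(c(1, 0))),
                 "excluded")
  expect_length(re$errors$pi, 1L)   # only the nonzero true entry remains
  expect_equal(re$errors$pi, -50, tolerance = 1e-10)
})

test_that("IQR summary uses linear-interpolation quantiles", {
  e <- c(-20, -10, 0, 10, 40)
  expect_equal(diff(quantile(e, c(0.25, 0.75), type = 7, names = FALSE)), 20)
})

test_that("ancestral accuracy counts (family, internal node) matches", {
  tr <- tree4()
  ints <- internal_nodes(tr)          # 3 internal nodes
  truth <- list(states = matrix(1L, tr$n_node, 2L))
  est <- truth$states
  est[ints[1L], 1L] <- 2L             # one wrong ancestral state of 6
  hist <- structure(list(states = est, tree = tr), class = "gcevo_history")
  expect_equal(ancestral_accuracy(hist, truth), 100 * 5 / 6)
  # presence/absence collapses 1 vs 2 into the same class
  expect_equal(ancestral_accuracy(hist, truth, presence_absence = TRUE), 100)
  # per-family scoring: family 1 has an error, family 2 does not
  expect_equal(ancestral_accuracy(hist, truth, per_family = TRUE), 50)
})

test_that("event-count correlation is the Pearson coefficient x 100", {
  tr <- tree4()
  h <- structure(list(total_gains = c(1, 2, 3, 5), total_losses = c(0, 1, 1, 2),
                      tree = tr), class = "gcevo_history")
  tru <- list(total_gains = c(1, 3, 3, 6), total_losses = c(1, 1, 2, 3))
  expect_equal(event_count_correlation(h, tru),
               100 * cor(c(1, 3, 4, 7), c(2, 4, 5, 9)))
  same <- list(total_gains = c(2, 2, 2, 2), total_losses = c(1, 1, 1, 1))
  expect_warning(r <- event_count_correlation(h, same), "zero variance")
  expect_true(is.na(r))
})

test_that("normalized cluster rates divide by the slowest cluster", {
  rates <- list(build_rate_matrix("bd", list(alpha = 0.2, beta = 0.4), 1L),
                build_rate_matrix("bd", list(alpha = 1.0, beta = 2.0), 1L))
  theta <- mixture_params("bd", "pm", K = 2L, lmax = 1L, phi = c(0.5, 0.5),
                          rates = rates, pi = rbind(c(0.5, 0.5), c(0.5, 0.5)))
  # cluster rate = |sum_i pi_i R_ii| = 0.5*0.2 + 0.5*0.4 etc.
  r <- normalized_cluster_rates(theta)
  expect_equal(r, c(1, 5), tolerance = 1e-12)
  expect_equal(min(r), 1)
})

test_that("by_family holdout partitions families at the requested ratio", {
  set.seed(73)
  tr <- as_gcevo_tree(ape::rcoal(8))
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  sim <- simulate_dataset(theta, tr, L = 50L)
  sp <- split_holdout(sim$table, tr, "by_family", ratio = 0.8, seed = 731L)
  expect_equal(ncol(sp$train$table), 40L)
  expect_equal(ncol(sp$test$table), 10L)
  expect_length(intersect(colnames(sp$train$table), colnames(sp$test$table)), 0L)
  expect_setequal(c(colnames(sp$train$table), colnames(sp$test$table)),
                  colnames(sim$table))
  # both halves keep the full tree
  expect_equal(sp$train$tree$n_tip, 8L)
  # and can be scored / refitted directly
  expect_true(is.finite(heldout_loglik(theta, sp$test$table, sp$test$tree)))
})

test_that("by_species holdout prunes the tree but preserves leaf-to-leaf distances", {
  set.seed(74)
  tr <- as_gcevo_tree(ape::rcoal(10))
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  sim <- simulate_dataset(theta, tr, L = 30L)
  sp <- split_holdout(sim$table, tr, "by_species", ratio = 0.5, seed = 741L)
  expect_equal(sort(c(rownames(sp$train$table), rownames(sp$test$table))),
               sort(tip_labels(tr)))
  full_d <- ape::cophenetic.phylo(gcevo_tree_to_phylo(tr))
  for (part in sp) {
    expect_equal(rownames(part$table), tip_labels(part$tree))
    expect_equal(ncol(part$table), 30L)
    sub_d <- ape::cophenetic.phylo(gcevo_tree_to_phylo(part$tree))
    keep <- rownames(sub_d)
    expect_equal(sub_d, full_d[keep, keep], tolerance = 1e-9)
  }
})

test_that("disjoint holdout shares no family between train and test", {
  set.seed(75)
  tr <- as_gcevo_tree(ape::rcoal(10))
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  sim <- simulate_dataset(theta, tr, L = 60L)
  sp <- split_holdout(sim$table, tr, "disjoint", ratio = 0.5, seed = 751L)
  expect_length(intersect(colnames(sp$train$table), colnames(sp$test$table)), 0L)
  # no all-zero families survive in either part
  for (part in sp) expect_true(all(colSums(part$table) > 0))
})

test_that("split_holdout validates its arguments", {
  tr <- tree4()
  tab <- ortholog_table(matrix(1L, 4, 3, dimnames = list(tip_labels(tr),
                                                         paste0("f", 1:3))))
  expect_error(split_holdout(tab, tr, "by_family", ratio = 1.2), "ratio")
  expect_error(split_holdout(tab, tr, "by_species", ratio = 0.9),
               "at least 2 leaves")
})
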