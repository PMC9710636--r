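# simulator: topologies, Yule branch lengths, Gillespie forward simulation

test_that("perfect_binary_tree builds power-of-two topologies", {
  tr <- perfect_binary_tree(8L)
  expect_equal(tr$n_tip, 8L)
  expect_equal(tr$n_node, 15L)
  expect_setequal(tip_labels(tr), paste0("s", 1:8))
  expect_error(perfect_binary_tree(6L), "power of two")
  expect_error(perfect_binary_tree(1L))
})

test_that("Yule trees are ultrametric with increasing split times", {
  set.seed(61)
  topo <- perfect_binary_tree(16L)
  tr <- yule_branch_lengths(topo, 2.0)
  # depth of every leaf from the root is identical
  depth <- numeric(tr$n_node)
  for (m in rev(branch_nodes(tr))) depth[m] <- depth[tr$parent[m]] + tr$brlen[m]
  leaf_depths <- depth[tr$is_tip]
  expect_lt(diff(range(leaf_depths)), 1e-10)
  expect_true(all(tr$brlen[branch_nodes(tr)] > 0))
  expect_error(yule_branch_lengths(topo, -1))
})

test_that("Yule tree depth matches the analytic expectation", {
  # depth = sum of waiting times Exp(k*lambda), k = 2..N:
  # mean sum 1/(k lambda), variance sum 1/(k lambda)^2
  set.seed(62)
  N <- 16L; lambda <- 3.0; nrep <- 600L
  topo <- perfect_binary_tree(N)
  depths <- replicate(nrep, {
    tr <- yule_branch_lengths(topo, lambda)
    d <- 0
    m <- 1L                      # any leaf; tree is ultrametric
    while (m < tr$n_node) {
      d <- d + tr$brlen[m]
      m <- tr$parent[m]
    }
    d
  })
  mu <- sum(1 / ((2:N) * lambda))
  sdv <- sqrt(sum(1 / ((2:N) * lambda)^2))
  expect_lt(abs(mean(depths) - mu), 4 * sdv / sqrt(nrep))
})

test_that("single-branch endpoint distribution matches exp(tR)", {
  set.seed(63)
  rm <- build_rate_matrix("bdard",
                          list(gain = c(0.9, 0.5), loss = c(1.1, 0.7)), 2L)
  gv <- rate_gains(rm); lv <- rate_losses(rm)
  t <- 0.7; a <- 1L; n <- 20000L
  ends <- replicate(n, simulate_branch(a, gv, lv, 2L, t)[1L])
  emp <- tabulate(ends + 1L, nbins = 3L)
  p <- transition_matrix(rm, t)[a + 1L, ]
  chisq <- sum((emp - n * p)^2 / (n * p))
  # 2 degrees of freedom; bound at the 99.99% quantile
  expect_lt(chisq, qchisq(0.9999, df = 2))
})

test_that("simulate_branch respects the 0..lmax bounds and counts events", {
  set.seed(64)
  for (i in 1:200) {
    res <- simulate_branch(sample(0:2, 1L), c(2, 2), c(3, 3), 2L, 0.5)
    expect_true(res[1L] >= 0 && res[1L] <= 2)
    expect_true(all(res[2:3] >= 0))
  }
  # an absorbing case: no rates out of state 0
  res <- simulate_branch(0L, c(0, 0), c(5, 5), 2L, 10)
  expect_equal(res, c(0, 0, 0))
})

test_that("simulated cluster and root-state frequencies follow theta", {
  set.seed(65)
  tr <- yule_branch_lengths(perfect_binary_tree(8L), 3.0)
  theta <- mixture_params(
    "bd", "pm", K = 2L, lmax = 2L, phi = c(0.7, 0.3),
    rates = list(build_rate_matrix("bd", list(alpha = 0.5, beta = 0.6), 2L),
                 build_rate_matrix("bd", list(alpha = 1.2, beta = 0.9), 2L)),
    pi = rbind(c(0.6, 0.3, 0.1), c(0.1, 0.3, 0.6)))
  L <- 4000L
  sim <- simulate_dataset(theta, tr, L, seed = 651L)
  # cluster frequencies: 4-SE binomial check
  f1 <- mean(sim$truth$cluster == 1L)
  expect_lt(abs(f1 - 0.7), 4 * sqrt(0.7 * 0.3 / L))
  # root states within each cluster follow that cluster's pi
  root <- tree_root(tr)
  for (k in 1:2) {
    idx <- sim$truth$cluster == k
    emp <- tabulate(sim$truth$states[root, idx] + 1L, nbins = 3L) / sum(idx)
    pk <- theta$pi[k, ]
    expect_lt(max(abs(emp - pk)), 4 * sqrt(max(pk * (1 - pk)) / sum(idx)))
  }
})

test_that("recorded truth is internally consistent", {
  set.seed(66)
  tr <- as_gcevo_tree(ape::rcoal(8))
  theta <- random_theta("bdard", "pm", K = 2L, lmax = 3L)
  sim <- simulate_dataset(theta, tr, L = 50L)
  expect_s3_class(sim$table, "gcevo_table")
  expect_equal(rownames(sim$table), tip_labels(tr))
  # the table is exactly the leaf rows of the true state matrix
  expect_equal(unname(unclass(sim$table)),
               unname(sim$truth$states[tr$is_tip, ]))
  expect_equal(sim$truth$total_gains, colSums(sim$truth$gains))
  expect_equal(sim$truth$total_losses, colSums(sim$truth$losses))
  # net change along each branch equals gains - losses
  for (m in branch_nodes(tr)) {
    expect_equal(sim$truth$states[m, ] - sim$truth$states[tr$parent[m], ],
                 sim$truth$gains[m, ] - sim$truth$losses[m, ])
  }
  # identical seed reproduces the dataset
  sim3 <- simulate_dataset(theta, tr, L = 50L, seed = 660L)
  sim4 <- simulate_dataset(theta, tr, L = 50L, seed = 660L)
  expect_equal(unclass(sim3$table), unclass(sim4$table))
})

test_that("write_truth emits one labelled row per family", {
  set.seed(67)
  tr <- tree4()
  theta <- random_theta("bd", "pm", K = 2L, lmax = 2L)
  sim <- simulate_dataset(theta, tr, L = 6L)
  f <- tempfile(fileext = ".tsv")
  write_truth(sim, f)
  df <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(df), 6L)
  expect_true(all(c("FamilyID", "cluster", "total_gains", "total_losses",
                    tr$labels) %in% colnames(df)))
  expect_equal(df$cluster, sim$truth$cluster)
  expect_equal(as.integer(df$A),
               unname(sim$truth$states[which(tr$labels == "A"), ]))
})
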