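test_that("modularity matches closed forms on hand-checkable graphs", {
  w <- two_triangles()
  # components partition of two unit triangles at gamma 1
  expect_equal(modularity_q(w, c(1, 1, 1, 2, 2, 2), gamma = 1), 0.5)
  # one community: Q = 1 - gamma for any graph
  for (g in c(0, 0.5, 0.9, 1.3))
    expect_equal(modularity_q(w, rep(1, 6), gamma = g), 1 - g,
                 tolerance = 1e-12)
  # all singletons with zero diagonal: Q = -gamma * sum (k/2m)^2
  k <- rowSums(w)
  expect_equal(modularity_q(w, 1:6, gamma = 0.7),
               -0.7 * sum((k / sum(k))^2), tolerance = 1e-12)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "all-zero")
})

test_that("modularity is invariant to relabeling and patient reordering", {
  set.seed(2)
  w <- random_graph(10)
  labels <- sample(1:3, 10, TRUE)
  q0 <- modularity_q(w, labels, gamma = 0.9)
  expect_equal(modularity_q(w, 4 - labels, gamma = 0.9), q0, tolerance = 1e-12)
  idx <- sample(10)
  expect_equal(modularity_q(w[idx, idx], labels[idx], gamma = 0.9), q0,
               tolerance = 1e-12)
})

test_that("modularity agrees with an independent graph-library implementation", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:5) {
    w <- random_graph(12)
    labels <- sample(1:3, 12, TRUE)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    q_ref <- igraph::modularity(g, labels, weights = igraph::E(g)$weight,
                                resolution = 0.8)
    expect_equal(modularity_q(w, labels, gamma = 0.8), q_ref,
                 tolerance = 1e-10)
  }
})

test_that("louvain recovers the components of disconnected triangles", {
  p <- louvain(two_triangles(), gamma = 1, seed = 7)
  expect_equal(n_communities(p), 2)
  expect_equal(p$q, 0.5)
  expect_equal(length(unique(p$labels[1:3])), 1)
  expect_equal(length(unique(p$labels[4:6])), 1)
  expect_true(all(p$vote_fraction == 1))
  expect_setequal(unique(p$labels), 0:1)   # contiguous 0-based ids
})

test_that("large gamma forces the all-singleton partition", {
  w <- two_triangles()
  k <- rowSums(w)
  m2 <- sum(k)
  gamma_big <- max(m2 * w / outer(k, k)) + 0.1
  p <- louvain(w, gamma = gamma_big, seed = 1)
  expect_equal(n_communities(p), 6)
})

test_that("louvain is deterministic given a seed and never beats brute force", {
  set.seed(14)
  ok <- 0
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    w <- random_graph(n)
    q_star <- brute_force_modularity(w, gamma = 1)
    qs <- vapply(1:30, function(s) louvain(w, gamma = 1, seed = s)$q, 0)
    expect_lte(max(qs), q_star + 1e-9)
    if (max(qs) >= q_star - 1e-9) ok <- ok + 1
  }
  expect_gte(ok, 13)  # best-of-30 hits the optimum almost always
  p1 <- louvain(random_graph(10), gamma = 1, seed = 99)
  p2 <- louvain(random_graph(10), gamma = 1, seed = 99)
  # same seed inside louvain, but different graphs -> only labels structure
  w <- random_graph(10)
  expect_identical(louvain(w, seed = 123)$labels, louvain(w, seed = 123)$labels)
})

test_that("louvain Q dominates the trivial partitions", {
  set.seed(6)
  for (rep in 1:10) {
    w <- random_graph(12, p_edge = 0.4)
    p <- louvain(w, gamma = 0.9, seed = rep)
    k <- rowSums(w)
    q_singletons <- modularity_q(w, 1:12, gamma = 0.9)
    expect_gte(p$q, max(q_singletons, 1 - 0.9) - 1e-9)
  }
})

test_that("negative weights are clipped by default, with signed option", {
  w <- two_triangles()
  w[1, 4] <- w[4, 1] <- -0.5
  p <- louvain(w, gamma = 1, seed = 1)
  expect_equal(p$q, 0.5)  # clipped graph is the two triangles again
  expect_gt(p$clipped_fraction, 0)
  # signed scoring: the triangle partition keeps the negative edge between
  # communities and beats the single community, which absorbs it
  q_signed <- modularity_q(w, p$labels, gamma = 1, negative = "signed")
  q_signed_one <- modularity_q(w, rep(1, 6), gamma = 1, negative = "signed")
  expect_gt(q_signed, q_signed_one)
  p_s <- louvain(w, gamma = 1, seed = 1, negative = "signed")
  expect_equal(n_communities(p_s), 2)
})

test_that("majority voting aligns labels and records vote fractions", {
  # three constructed runs: subject 4 flips community in one run,
  # run labels permuted relative to each other
  runs <- list(c(0L, 0L, 1L, 1L, 1L),
               c(1L, 1L, 0L, 0L, 0L),    # same partition, relabeled
               c(0L, 0L, 1L, 0L, 1L))    # subject 4 defects
  v <- atrophynet:::vote_from_runs(runs, qs = c(0.3, 0.2, 0.1))
  expect_equal(v$labels, c(0L, 0L, 1L, 1L, 1L))
  expect_equal(v$vote_fraction, c(1, 1, 1, 2 / 3, 1))
})

test_that("consensus is deterministic and unanimous on trivially modular graphs", {
  w <- two_triangles()
  c1 <- consensus_vote(w, gamma = 1, n_runs = 20, seed = 5)
  c2 <- consensus_vote(w, gamma = 1, n_runs = 20, seed = 5)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$vote_fraction, c2$vote_fraction)
  expect_true(all(c1$vote_fraction == 1))
  expect_equal(c1$q, 0.5)
  expect_equal(c1$n_runs, 20L)
})

test_that("consensus Q is not degraded relative to single runs on planted data", {
  set.seed(10)
  z <- planted_block_z(k = 3, per = 8, noise = 0.3)
  sim <- correlation_similarity(patterns_from_z(z))
  cons <- consensus_vote(sim, gamma = 1, n_runs = 25, seed = 2)
  single_qs <- vapply(1:25, function(s)
    louvain(sim, gamma = 1, seed = s)$q, 0)
  expect_gte(cons$q, mean(single_qs) - 0.02)
})

test_that("gamma tuning reaches a target community count", {
  set.seed(11)
  z <- planted_block_z(k = 3, per = 8, noise = 0.2)
  sim <- correlation_similarity(patterns_from_z(z))
  tuned <- tune_gamma(sim, k_target = 3, n_runs = 10, seed = 3)
  expect_equal(n_communities(tuned$partition), 3)
  expect_true(tuned$gamma %in% seq(0.5, 1.5, by = 0.05))
  # singleton grid returns its only value
  t1 <- tune_gamma(sim, k_target = 3, gamma_grid = 0.9, n_runs = 5, seed = 4)
  expect_equal(t1$gamma, 0.9)
  # gamma = 0 removes the null-model penalty: on a connected graph the
  # whole-graph community is optimal
  set.seed(16)
  w_conn <- random_graph(12, p_edge = 1)
  t0 <- tune_gamma(w_conn, k_target = 1, gamma_grid = 0, n_runs = 5, seed = 5)
  expect_equal(n_communities(t0$partition), 1)
})

test_that("hierarchical comparator clusters blocks and scores Q on the shared graph", {
  set.seed(12)
  z <- planted_block_z(k = 2, per = 6, noise = 0.1)
  rownames(z) <- paste0("p", seq_len(nrow(z)))
  pat <- patterns_from_z(z)
  truth <- rep(1:2, each = 6)
  for (metric in c("correlation", "euclidean")) {
    p <- hierarchical_subtype(pat, metric = metric, k = 2)
    expect_equal(ari(p$labels, truth), 1)
    expect_equal(p$n_runs, 1L)
  }
  # k = n gives all singletons
  expect_equal(n_communities(hierarchical_subtype(pat, "correlation", k = 12)),
               12)
  expect_error(hierarchical_subtype(pat, "euclidean", k = 2, linkage = "no-such"),
               "linkage|method")
})

test_that("correlation and euclidean hierarchical partitions diverge under a severity confound", {
  set.seed(13)
  z <- planted_block_z(k = 2, per = 10, noise = 0.2)
  z <- z + rnorm(nrow(z), 0, 1.5)    # strong per-patient severity axis
  pat <- patterns_from_z(z)
  pc <- hierarchical_subtype(pat, "correlation", k = 2)
  pe <- hierarchical_subtype(pat, "euclidean", k = 2)
  expect_lt(ari(pc$labels, pe$labels), 1)
  expect_equal(ari(pc$labels, rep(1:2, each = 10)), 1)
})
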