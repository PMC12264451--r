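test_that("sparsity thresholding keeps the exact edge count and top edges", {
  nc <- gen_nc_uptake(40, seed = 1)
  ref <- build_nc_reference(nc)
  net <- build_individual_network(ref$mu + rnorm(56) * ref$sigma, ref)

  for (s in sparsity_grid()) {
    g <- threshold_by_sparsity(net, s)
    expect_equal(sum(g$adjacency) / 2, round(s * 1540))
    expect_true(all(diag(g$adjacency) == 0))
    expect_identical(g$adjacency, t(g$adjacency))
  }
  # a known top-5 edge set is selected exactly (brute-force sort of weights)
  W <- net$W
  ut <- which(upper.tri(W), arr.ind = TRUE)
  top5 <- ut[order(-abs(W[ut]))[1:5], , drop = FALSE]
  g5 <- threshold_by_sparsity(net, 5 / 1540)
  expect_equal(sum(g5$adjacency) / 2, 5)
  expect_true(all(g5$adjacency[top5] == 1))
  expect_error(threshold_by_sparsity(net, 0), "sparsity")
  expect_error(threshold_by_sparsity(net, 1), "sparsity")
})

test_that("nodal metrics match closed forms and hand counts", {
  # complete K5
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  nm <- nodal_metrics(make_binary_graph(K5))
  expect_equal(nm$dc, rep(4, 5))
  expect_equal(nm$ncf, rep(1, 5))
  # star with 5 leaves
  S <- matrix(0L, 6, 6); S[1, 2:6] <- 1L; S <- S + t(S)
  nm2 <- nodal_metrics(make_binary_graph(S), nodes = 1)
  expect_equal(nm2$dc, 5)
  expect_equal(nm2$ncf, 0)
  # triangle with a pendant on node 1: Dc = 3, Ncf = 1/3
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- A[1, 4] <- 1L
  A <- A + t(A)
  nm3 <- nodal_metrics(make_binary_graph(A), nodes = 1)
  expect_equal(nm3$dc, 3)
  expect_equal(nm3$ncf, 1 / 3)
})

test_that("global metrics match closed forms and enumeration", {
  K10 <- matrix(1L, 10, 10); diag(K10) <- 0L
  gm <- global_metrics(make_binary_graph(K10))
  expect_equal(gm$e_global, 1)
  expect_equal(gm$e_local, 1)
  expect_equal(gm$c_mean, 1)
  expect_equal(gm$l_char, 1)

  # path a-b-c: pairs at distance 1, 1, 2 -> e_global = 5/6
  P3 <- matrix(0L, 3, 3); P3[1, 2] <- P3[2, 3] <- 1L; P3 <- P3 + t(P3)
  expect_equal(global_metrics(make_binary_graph(P3))$e_global, 5 / 6)

  # two disjoint K2: only 2 of 6 ordered pairs connected -> 1/3
  D <- matrix(0L, 4, 4); D[1, 2] <- D[3, 4] <- 1L; D <- D + t(D)
  expect_equal(global_metrics(make_binary_graph(D))$e_global, 1 / 3)
})

test_that("all metrics agree with exhaustive enumeration on small graphs", {
  for (seed in 1:12) {
    n <- sample(5:12, 1)
    A <- random_adjacency(n, runif(1, 0.25, 0.7), seed = 100 + seed)
    g <- make_binary_graph(A)
    gm <- global_metrics(g)
    expect_equal(gm$e_global, oracle_global_efficiency(A), tolerance = 1e-12)
    expect_equal(gm$l_char, oracle_char_path(A), tolerance = 1e-12)
    expect_equal(gm$e_local, oracle_local_efficiency(A), tolerance = 1e-12)
    nm <- nodal_metrics(g)
    expect_equal(nm$dc, rowSums(A), ignore_attr = TRUE)
    for (i in seq_len(n)) {
      expect_equal(nm$ncf[i], oracle_node_clustering(A, i), tolerance = 1e-12)
    }
    expect_equal(gm$c_mean,
                 mean(vapply(seq_len(n), function(i)
                   oracle_node_clustering(A, i), numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("rewiring preserves the degree sequence and is seeded", {
  A <- random_adjacency(20, 0.3, seed = 7)
  g <- make_binary_graph(A)
  r1 <- random_reference_graph(g, seed = 42)
  r2 <- random_reference_graph(g, seed = 42)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_equal(rowSums(r1$adjacency), rowSums(A))
  expect_false(identical(r1$adjacency, A))  # enough swaps to move
  # complete graph cannot swap: returned unchanged with a flag
  K6 <- matrix(1L, 6, 6); diag(K6) <- 0L
  rk <- random_reference_graph(make_binary_graph(K6), seed = 1)
  expect_true(isTRUE(attr(rk, "rewire_warning")))
  expect_identical(rk$adjacency, K6)
})

test_that("heavy rewiring of a ring lattice destroys clustering", {
  # ring lattice, n = 30, k = 4 neighbours per side -> C = 0.5
  n <- 30
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i - 1 + d) %% n) + 1
    A[i, j] <- A[j, i] <- 1L
  }
  g <- make_binary_graph(A)
  c0 <- global_metrics(g)$c_mean
  cr <- mean(vapply(1:5, function(s) {
    global_metrics(random_reference_graph(g, n_rewires = 20 * g$n_edges,
                                          seed = s))$c_mean
  }, numeric(1)))
  er <- 4 / (n - 1)    # ER expectation at matched density
  expect_gt(c0, 0.45)
  expect_lt(cr, c0 / 2)
  expect_lt(abs(cr - er), 0.1)
})

test_that("small-world indices are ~1 for random graphs, > 1 for lattices", {
  # ER-like graph normalizes to itself
  A <- random_adjacency(56, 0.3, seed = 11)
  g <- make_binary_graph(A)
  sw <- small_world_indices(g, n_rand = 40, seed = 3)
  expect_lt(abs(sw$gamma - 1), 0.15)
  expect_lt(abs(sw$lambda - 1), 0.15)
  expect_lt(abs(sw$sigma - 1), 0.15)
  # complete graph is its own rewiring: exactly 1
  K8 <- matrix(1L, 8, 8); diag(K8) <- 0L
  swk <- small_world_indices(make_binary_graph(K8), n_rand = 5, seed = 1)
  expect_equal(swk$gamma, 1)
  expect_equal(swk$lambda, 1)
  expect_equal(swk$sigma, 1)
  # ring lattice: strongly clustered, sigma > 1
  n <- 56
  L <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in 1:4) {
    j <- ((i - 1 + d) %% n) + 1
    L[i, j] <- L[j, i] <- 1L
  }
  swl <- small_world_indices(make_binary_graph(L), n_rand = 20, seed = 5)
  expect_gt(swl$sigma, 1.5)
})

test_that("profile aggregation is the mean curve height; constants persist", {
  expect_equal(tpenet:::trapezoid_aggregate(sparsity_grid(), rep(3.5, 10)), 3.5)
  expect_equal(tpenet:::trapezoid_aggregate(c(0.2, 0.4), c(1, 2)), 1.5)
  expect_length(sparsity_grid(), 10)

  nc <- gen_nc_uptake(40, seed = 2)
  ref <- build_nc_reference(nc)
  net <- build_individual_network(ref$mu + rnorm(56, 0, 0.5) * ref$sigma, ref)
  prof <- graph_feature_profile(net, n_rand = 5, seed = 9)
  expect_named(prof, feature_columns()[1:9])
  expect_true(all(is.finite(prof)))
  per <- attr(prof, "per_sparsity")
  expect_equal(dim(per), c(9, 10))
  # e_global nondecreasing in sparsity on nested thresholded graphs
  expect_true(all(diff(per["e_global", ]) >= 0))
  # aggregate equals the trapezoid of the per-sparsity curve
  expect_equal(unname(prof["e_global"]),
               tpenet:::trapezoid_aggregate(sparsity_grid(), per["e_global", ]))
  # the insula-only fast path agrees with the full profile
  fast <- insula_feature_profile(net)
  expect_equal(fast, prof[c("dc_aIns", "dc_pIns", "ncf_aIns", "ncf_pIns")],
               tolerance = 1e-12)
})
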