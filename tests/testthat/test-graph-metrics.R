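test_that("symmetrization collapses reciprocal pairs and drops self-loops", {
  e <- data.frame(pre = c("a", "b", "a", "c"), post = c("b", "a", "a", "d"))
  g <- symmetrize(e, nodes = c("a", "b", "c", "d"))
  expect_equal(nrow(g$edges), 2)       # {a,b} once, {c,d}; self-loop a->a gone
  expect_equal(g$n_links, 3)           # directed links net of self-loops
  expect_equal(sort(g$adj[[1]]), 2)    # a's only neighbour is b
})

test_that("path lengths match closed forms and a Floyd-Warshall oracle", {
  # complete graph: all distances 1
  A <- matrix(1, 10, 10); diag(A) <- 0
  g <- dg_graph_from_adjacency(A)
  expect_equal(avg_path_length(g)$L, 1)

  # path graph a-b-c: L_i = {1.5, 1, 1.5}, L = 4/3
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  res <- avg_path_length(dg_graph_from_adjacency(P))
  expect_equal(res$Li, c(1.5, 1, 1.5))
  expect_equal(res$L, 4 / 3)

  # oracle equivalence on random connected graphs
  set.seed(1234)
  for (rep in 1:50) {
    A <- random_connected_graph(sample(5:30, 1))
    D <- oracle_apsp(A)
    got <- avg_path_length(dg_graph_from_adjacency(A))
    want_Li <- rowSums(D) / (nrow(A) - 1)
    expect_equal(got$Li, want_Li)
    expect_equal(got$L, mean(want_Li))
  }
})

test_that("disconnected graphs are rejected with the offending pair", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_error(avg_path_length(dg_graph_from_adjacency(A)), "disconnected")
})

test_that("clustering matches exhaustive triangle counting", {
  # K5 fully clustered
  A <- matrix(1, 5, 5); diag(A) <- 0
  expect_equal(clustering_coeff(dg_graph_from_adjacency(A))$C, 1)

  # star: no neighbour-neighbour edges
  S <- matrix(0, 6, 6); S[1, 2:6] <- S[2:6, 1] <- 1
  expect_equal(clustering_coeff(dg_graph_from_adjacency(S))$C, 0)

  # triangle plus pendant: C_i = {1, 1, 1/3, 0} -> C = 7/12 (the vertex
  # carrying the pendant has 3 neighbours with one edge among them)
  T4 <- matrix(0, 4, 4)
  T4[1, 2] <- T4[2, 1] <- T4[2, 3] <- T4[3, 2] <- T4[1, 3] <- T4[3, 1] <- 1
  T4[3, 4] <- T4[4, 3] <- 1
  got <- clustering_coeff(dg_graph_from_adjacency(T4))
  expect_equal(got$Ci, c(1, 1, 1 / 3, 0))
  expect_equal(got$C, 7 / 12)
  expect_equal(got$Ci, oracle_clustering(T4))

  set.seed(4321)
  for (rep in 1:50) {
    A <- random_connected_graph(sample(5:30, 1))
    got <- clustering_coeff(dg_graph_from_adjacency(A))
    expect_equal(got$Ci, oracle_clustering(A))
  }
})

test_that("ring lattice clustering matches its closed form", {
  # N = 20, k = 4 ring lattice: C = 3(k-2) / (4(k-1)) = 0.5
  n <- 20
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      j <- (i - 1 + d) %% n + 1
      A[i, j] <- A[j, i] <- 1
    }
  }
  g <- dg_graph_from_adjacency(A)
  expect_equal(clustering_coeff(g)$C, 0.5)
  expect_equal(2 * nrow(g$edges) / g$n, 4)
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(2026)
  for (rep in 1:30) {
    A <- random_connected_graph(sample(6:40, 1))
    g <- dg_graph_from_adjacency(A)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(avg_path_length(g)$L, igraph::mean_distance(ig))
    ci <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    expect_equal(clustering_coeff(g)$Ci, ci)
  }
})

test_that("random-graph reference follows the closed forms", {
  rr <- random_reference(100, 10)
  expect_equal(rr$C_rand, 0.1)
  expect_equal(rr$L_rand, 2)
  rr2 <- random_reference(exp(2), exp(1))
  expect_equal(rr2$L_rand, 2)
  expect_error(random_reference(100, 1), "mean degree")
  expect_error(random_reference(1, 5), "n > 1")
})

test_that("small-world quotient reproduces the worked example and is linear in C", {
  Q <- small_world_quotient(C = 0.2074, L = 2.0919,
                            C_rand = 0.0428, L_rand = 2.3015)
  expect_equal(round(as.numeric(Q), 4), 5.3313)

  expect_equal(as.numeric(small_world_quotient(0.3, 2, 0.3, 2)), 1)
  q1 <- as.numeric(small_world_quotient(0.1, 2, 0.05, 2.5))
  q2 <- as.numeric(small_world_quotient(0.2, 2, 0.05, 2.5))
  expect_equal(q2, 2 * q1)
  expect_error(small_world_quotient(0, 2, 0.05, 2.5), "positive")
})

test_that("mean degree counts directed links for directed connectivity", {
  net <- mini_network(seed = 2)
  st <- small_world_stats(net)
  expect_equal(st$mean_degree, 2 * nrow(net$edges) / nrow(net$populations))
  # undirected input falls back to 2E/N
  A <- matrix(1, 6, 6); diag(A) <- 0
  st2 <- small_world_stats(dg_graph_from_adjacency(A))
  expect_equal(st2$mean_degree, 5)
  expect_equal(st2$C, 1)
  expect_equal(st2$L, 1)
})
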