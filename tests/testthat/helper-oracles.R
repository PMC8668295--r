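# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately naive (brute force / exhaustive) and shares no code
# with the package implementation.

# Brute-force nearest-neighbour pool: all post cells sorted by axis
# distance (ties to the lower index), first `pool` kept, first `excl`
# of those removed.
oracle_pool <- function(pre_pos, post_pos, pool, excl = 0) {
  ord <- order(abs(post_pos - pre_pos), seq_along(post_pos))
  keep <- ord[seq_len(pool)]
  if (excl > 0) keep <- keep[-seq_len(excl)]
  keep
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix.
oracle_apsp <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# Exhaustive per-node clustering coefficient by neighbour-pair enumeration.
oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (A[nb[a], nb[b]] > 0) e <- e + 1
      }
    }
    2 * e / (k * (k - 1))
  })
}

# Random connected undirected graph as an adjacency matrix (attach each new
# node to a random earlier node, then sprinkle extra edges).
random_connected_graph <- function(n, extra = n) {
  A <- matrix(0L, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    A[i, j] <- A[j, i] <- 1L
  }
  for (e in seq_len(extra)) {
    ij <- sample.int(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1L
  }
  diag(A) <- 0L
  A
}

dg_graph_from_adjacency <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  edges <- data.frame(pre = paste0("n", idx[, 1]), post = paste0("n", idx[, 2]))
  symmetrize(edges, nodes = paste0("n", seq_len(nrow(A))))
}

# Miniature dentate network (20/3/2/2) used where full scale is not needed.
mini_counts <- c(GC = 20L, MC = 3L, BC = 2L, HIPP = 2L)

mini_rules <- function() {
  list(
    dg_rule("GC", "MC", 1L, 2L),
    dg_rule("GC", "BC", 1L, 2L),
    dg_rule("GC", "HIPP", 1L, 2L),
    dg_rule("MC", "GC", 5L, 10L, center_exclusion = 2L),
    dg_rule("MC", "MC", 1L, 3L),
    dg_rule("MC", "BC", 1L, 2L),
    dg_rule("MC", "HIPP", 1L, 2L),
    dg_rule("BC", "GC", 4L, 8L),
    dg_rule("BC", "MC", 1L, 3L),
    dg_rule("BC", "BC", 1L, 2L),
    dg_rule("HIPP", "GC", 5L, 10L),
    dg_rule("HIPP", "MC", 1L, 2L),
    dg_rule("HIPP", "BC", 1L, 2L)
  )
}

mini_network <- function(seed = 1L, ...) {
  generate_network(counts = mini_counts, rules = mini_rules(), seed = seed, ...)
}
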