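test_that("cell placement is even, deterministic and validated", {
  pops <- place_cells(c(GC = 500, MC = 15, BC = 6, HIPP = 6))
  expect_equal(nrow(pops), 527)
  gc <- pops[pops$type == "GC", ]
  expect_equal(gc$pos, (0:499 + 0.5) / 500)
  expect_true(all(diff(gc$pos) > 0))

  ones <- place_cells(c(GC = 1, MC = 1, BC = 1, HIPP = 1))
  expect_equal(ones$pos, rep(0.5, 4))

  mc <- place_cells(c(GC = 10, MC = 2, BC = 1, HIPP = 1))
  expect_equal(mc$pos[mc$type == "MC"], c(0.25, 0.75))

  expect_error(place_cells(c(GC = 0, MC = 1, BC = 1, HIPP = 1)), "positive")
  expect_error(place_cells(c(GC = 10, MC = 2, BC = 1)), "four types")
})

test_that("target selection matches an exhaustive nearest-neighbour oracle", {
  pops <- place_cells(c(GC = 10, MC = 1, BC = 1, HIPP = 1))
  # one MC at the axis center, pool 4, no exclusion, divergence 4:
  # must return exactly the 4 nearest GCs
  rule <- dg_rule("MC", "GC", 4L, 4L)
  set.seed(99)
  got <- sort(select_targets(rule, "MC0", pops))
  gc_pos <- pops$pos[pops$type == "GC"]
  want <- sort(paste0("GC", oracle_pool(0.5, gc_pos, 4) - 1))
  expect_equal(got, want)

  # with a centre exclusion, chosen targets avoid the excluded zone and
  # stay inside the pool window, for every pre cell
  pops2 <- place_cells(c(GC = 50, MC = 5, BC = 1, HIPP = 1))
  rule2 <- dg_rule("MC", "GC", 6L, 20L, center_exclusion = 4L)
  gc_pos2 <- pops2$pos[pops2$type == "GC"]
  mc_pos2 <- pops2$pos[pops2$type == "MC"]
  set.seed(7)
  for (i in seq_along(mc_pos2)) {
    got <- select_targets(rule2, paste0("MC", i - 1), pops2)
    allowed <- paste0("GC", oracle_pool(mc_pos2[i], gc_pos2, 20, 4) - 1)
    expect_length(got, 6)
    expect_length(unique(got), 6)
    expect_true(all(got %in% allowed))
  }

  # divergence 0 gives no targets
  expect_equal(select_targets(dg_rule("MC", "GC", 0L, 4L), "MC0", pops),
               character(0))
})

test_that("rule invariants are enforced at construction", {
  expect_error(dg_rule("MC", "GC", 10L, 9L), "infeasible")
  expect_error(dg_rule("MC", "GC", 5L, 10L, center_exclusion = 10L),
               "center_exclusion")
  expect_error(dg_rule("MC", "GC", -1L, 10L), "non-negative")
})

test_that("every pre cell realizes its divergence exactly and edges conserve", {
  net <- generate_network(seed = 3)
  for (rule in net$rules) {
    e <- net$edges[net$edges$synapse_ref == rule$synapse_ref, ]
    outdeg <- table(e$pre)
    expect_equal(length(outdeg), net$counts[[rule$pre]])
    expect_true(all(outdeg == rule$divergence),
                label = sprintf("out-degree for %s->%s", rule$pre, rule$post))
    # per-rule simple graph: no duplicated (pre, post), no autapses
    expect_false(any(duplicated(e[, c("pre", "post")])))
    if (!rule$allow_self) expect_false(any(e$pre == e$post))
  }
  s <- connectivity_summary(net)
  for (rule in net$rules) {
    row <- s[s$pre_type == rule$pre & s$post_type == rule$post, ]
    expect_equal(row$convergence_mean,
                 net$counts[[rule$pre]] * rule$divergence / net$counts[[rule$post]])
  }
})

test_that("targets honour the topographic pool window (independent scan)", {
  net <- mini_network(seed = 11)
  pops <- net$populations
  pos <- setNames(pops$pos, pops$cell)
  for (rule in net$rules) {
    e <- net$edges[net$edges$synapse_ref == rule$synapse_ref, ]
    post_cells <- pops$cell[pops$type == rule$post]
    post_pos <- pops$pos[pops$type == rule$post]
    for (pre in unique(e$pre)) {
      allowed <- post_cells[oracle_pool(pos[[pre]], post_pos,
                                        rule$pool_size, rule$center_exclusion)]
      if (!rule$allow_self) allowed <- setdiff(allowed, pre)
      expect_true(all(e$post[e$pre == pre] %in% allowed),
                  label = sprintf("pool window %s->%s (%s)",
                                  rule$pre, rule$post, pre))
    }
  }
})

test_that("healthy mode has no GC-GC or BC-HIPP edges and active mossy cells", {
  net <- generate_network(seed = 5)
  expect_equal(sum(net$edges$pre_type == "GC" & net$edges$post_type == "GC"), 0)
  expect_equal(sum(net$edges$pre_type == "BC" & net$edges$post_type == "HIPP"), 0)
  mc_out <- table(net$edges$pre[net$edges$pre_type == "MC"])
  expect_equal(length(mc_out), 15)
  expect_true(all(mc_out > 0))
})

test_that("pathological mode adds sprouted edges and can delete mossy cells", {
  net <- generate_network(seed = 2, mode = "pathological",
                          sprouting_degree = 2, mc_loss = 0)
  gcgc <- net$edges[net$edges$pre_type == "GC" & net$edges$post_type == "GC", ]
  expect_equal(nrow(gcgc), 1000)
  expect_true(all(table(gcgc$pre) == 2))
  expect_false(any(gcgc$pre == gcgc$post))

  lesioned <- generate_network(seed = 2, mode = "pathological",
                               sprouting_degree = 2, mc_loss = 3)
  expect_length(lesioned$mc_deleted, 3)
  expect_false(any(lesioned$edges$pre %in% lesioned$mc_deleted))
  expect_false(any(lesioned$edges$post %in% lesioned$mc_deleted))
})

test_that("generation is reproducible and seed moves edges but not statistics", {
  a <- generate_network(seed = 42)
  b <- generate_network(seed = 42)
  expect_identical(a$edges, b$edges)

  c <- generate_network(seed = 43)
  expect_false(identical(a$edges, c$edges))
  sa <- connectivity_summary(a)
  sc <- connectivity_summary(c)
  expect_equal(sa[, c("pre_type", "post_type", "n_edges", "divergence_mean",
                      "convergence_mean")],
               sc[, c("pre_type", "post_type", "n_edges", "divergence_mean",
                      "convergence_mean")])
})

test_that("infeasible rules and unknown cells raise informative errors", {
  pops <- place_cells(c(GC = 10, MC = 2, BC = 1, HIPP = 1))
  # pool bigger than the population
  r <- dg_rule("MC", "GC", 5L, 11L)
  expect_error(select_targets(r, "MC0", pops), "pool_size")
  expect_error(select_targets(dg_rule("MC", "GC", 1L, 4L), "MC9", pops),
               "unknown")
  # self-removal can push candidates below the divergence
  tiny <- place_cells(c(GC = 1, MC = 2, BC = 1, HIPP = 1))
  expect_error(select_targets(dg_rule("MC", "MC", 2L, 2L), "MC0", tiny),
               "infeasible")
})
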