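#' Select postsynaptic targets for one presynaptic cell
#'
#' Realizes a topographic connection rule for a single presynaptic cell:
#' the candidate pool is the `pool_size` postsynaptic cells nearest to the
#' presynaptic cell's axis position (ties broken toward the lower index),
#' minus the `center_exclusion` nearest cells and, for same-type rules
#' without autapses, the cell itself.  Exactly `divergence` distinct targets
#' are sampled uniformly without replacement from that pool.  At the axis
#' boundaries the nearest-neighbour pool naturally clamps inside the
#' population; there is no wraparound.
#'
#' The caller is responsible for seeding the RNG (see [generate_network()],
#' which gives every rule its own deterministic substream).
#'
#' @param rule A [dg_rule].
#' @param pre_cell Cell id (e.g. `"MC3"`) of the presynaptic cell.
#' @param populations Cell table from [place_cells()].
#' @return Character vector of `divergence` postsynaptic cell ids.
#' @export
select_targets <- function(rule, pre_cell, populations) {
  i <- match(pre_cell, populations$cell)
  if (is.na(i)) stop("unknown presynaptic cell: ", pre_cell, call. = FALSE)
  if (populations$type[i] != rule$pre) {
    stop(sprintf("cell %s is not of the rule's presynaptic type %s",
                 pre_cell, rule$pre), call. = FALSE)
  }
  post <- populations[populations$type == rule$post, , drop = FALSE]
  select_targets_at(rule, populations$pos[i], pre_cell, post$pos, post$cell)
}

# Core of select_targets on raw vectors; post cells must be in index order.
select_targets_at <- function(rule, pre_pos, pre_cell, post_pos, post_ids) {
  if (rule$divergence == 0L) return(character(0))
  n_post <- length(post_pos)
  if (rule$pool_size > n_post) {
    stop(sprintf("rule %s: pool_size %d exceeds postsynaptic population size %d",
                 rule_label(rule), rule$pool_size, n_post), call. = FALSE)
  }
  ord <- order(abs(post_pos - pre_pos), seq_len(n_post))
  pool <- ord[seq_len(rule$pool_size)]
  if (rule$center_exclusion > 0L) {
    pool <- pool[-seq_len(rule$center_exclusion)]
  }
  if (!rule$allow_self && rule$pre == rule$post) {
    pool <- pool[post_ids[pool] != pre_cell]
  }
  if (length(pool) < rule$divergence) {
    stop(sprintf(
      "rule %s infeasible for cell %s: %d candidates after exclusions < divergence %d",
      rule_label(rule), pre_cell, length(pool), rule$divergence), call. = FALSE)
  }
  chosen <- pool[sample.int(length(pool), rule$divergence)]
  post_ids[chosen]
}

#' Generate the dentate gyrus connectivity graph
#'
#' Applies every connection rule to every presynaptic cell of its type,
#' producing a directed simple graph (per rule: no multi-edges, no autapses
#' unless the rule allows them).  In `"healthy"` mode granule cells are
#' never directly connected.  In `"pathological"` mode two lesions of the
#' epileptic dentate gyrus are emulated: mossy-fiber sprouting adds
#' `sprouting_degree` recurrent GC-to-GC connections per granule cell
#' (targets drawn from the `sprouting_pool` nearest granule cells), and
#' `mc_loss` randomly chosen mossy cells lose all their connections, both
#' afferent and efferent.
#'
#' Randomness is fully reproducible: each rule draws from its own substream
#' derived deterministically from `seed`, so the realized edges of one rule
#' are unaffected by the presence of other rules.
#'
#' @param counts Population sizes, as for [place_cells()].
#' @param mode `"healthy"` or `"pathological"`.
#' @param seed Integer seed.
#' @param rules List of [dg_rule] objects; defaults to [default_rules()].
#' @param sprouting_degree Recurrent GC-to-GC connections added per granule
#'   cell in pathological mode (default 2).
#' @param sprouting_pool Candidate-pool size for sprouted connections
#'   (default 100 nearest granule cells).
#' @param mc_loss Number of mossy cells whose connections are removed in
#'   pathological mode (default 0).
#' @return An object of class `dg_network`: list with elements
#'   `populations`, `edges` (data frame `pre`, `post`, `pre_type`,
#'   `post_type`, `synapse_ref`), `mode`, `seed`, `counts`, `rules`,
#'   `sprouting_degree`, `mc_deleted`.
#' @examples
#' net <- generate_network(seed = 1)
#' nrow(net$edges)  # 7228 directed connections
#' @export
generate_network <- function(counts = default_counts(),
                             mode = c("healthy", "pathological"),
                             seed = 1L,
                             rules = default_rules(),
                             sprouting_degree = 2L,
                             sprouting_pool = 100L,
                             mc_loss = 0L) {
  mode <- match.arg(mode)
  populations <- place_cells(counts)
  cts <- population_counts(populations)
  seed <- as.integer(seed)

  all_rules <- rules
  if (mode == "pathological" && sprouting_degree > 0L) {
    all_rules <- c(all_rules, list(
      dg_rule("GC", "GC", sprouting_degree, sprouting_pool,
              synapse_ref = "GC_GC_sprouted")))
  }
  if (mode == "healthy") {
    bad <- vapply(all_rules, function(r) r$pre == "GC" && r$post == "GC", logical(1))
    if (any(bad)) stop("healthy mode admits no GC->GC rule", call. = FALSE)
  }

  pos_by_type <- split(populations$pos, populations$type)
  ids_by_type <- split(populations$cell, populations$type)

  edge_sets <- lapply(all_rules, function(rule) {
    pre_ids <- ids_by_type[[rule$pre]]
    pre_pos <- pos_by_type[[rule$pre]]
    post_ids <- ids_by_type[[rule$post]]
    post_pos <- pos_by_type[[rule$post]]
    set.seed(rule_seed(seed, paste0(rule_label(rule), ":", rule$synapse_ref)))
    tgt <- vector("list", length(pre_ids))
    for (j in seq_along(pre_ids)) {
      tgt[[j]] <- select_targets_at(rule, pre_pos[j], pre_ids[j], post_pos, post_ids)
    }
    data.frame(
      pre  = rep(pre_ids, lengths(tgt)),
      post = unlist(tgt, use.names = FALSE),
      pre_type  = rule$pre,
      post_type = rule$post,
      synapse_ref = rule$synapse_ref,
      stringsAsFactors = FALSE
    )
  })
  edges <- if (length(edge_sets)) do.call(rbind, edge_sets) else
    data.frame(pre = character(0), post = character(0),
               pre_type = character(0), post_type = character(0),
               synapse_ref = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  mc_deleted <- character(0)
  if (mode == "pathological" && mc_loss > 0L) {
    if (mc_loss > cts[["MC"]]) {
      stop("mc_loss exceeds the mossy cell population", call. = FALSE)
    }
    set.seed(rule_seed(seed, "MC_loss"))
    mc_deleted <- ids_by_type[["MC"]][sample.int(cts[["MC"]], mc_loss)]
    keep <- !(edges$pre %in% mc_deleted) & !(edges$post %in% mc_deleted)
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }

  structure(
    list(populations = populations, edges = edges, mode = mode, seed = seed,
         counts = cts, rules = all_rules,
         sprouting_degree = if (mode == "pathological") as.integer(sprouting_degree) else 0L,
         mc_deleted = mc_deleted),
    class = "dg_network"
  )
}

#' @export
print.dg_network <- function(x, ...) {
  cat(sprintf("<dg_network> %s mode, seed %d\n", x$mode, x$seed))
  cat("  populations:",
      paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", "), "\n")
  cat(sprintf("  %d directed connections across %d rules\n",
              nrow(x$edges), length(x$rules)))
  if (length(x$mc_deleted)) {
    cat("  mossy cells deleted:", paste(x$mc_deleted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-projection connectivity statistics
#'
#' Divergence and convergence statistics for every realized (presynaptic
#' type, postsynaptic type) projection.  The divergence mean is taken over
#' all presynaptic cells of the type and the convergence mean and standard
#' deviation over all postsynaptic cells of the type, including cells with
#' zero inputs, so for a complete rule the convergence mean equals
#' `pre_count * divergence / post_count` exactly.
#'
#' @param network A `dg_network`.
#' @return Data frame with columns `pre_type`, `post_type`, `n_edges`,
#'   `divergence_mean`, `convergence_mean`, `convergence_sd`.
#' @examples
#' s <- connectivity_summary(generate_network(seed = 1))
#' s[s$pre_type == "MC" & s$post_type == "GC", "convergence_mean"]  # 6
#' @export
connectivity_summary <- function(network) {
  stopifnot(inherits(network, "dg_network"))
  edges <- network$edges
  cts <- network$counts
  pairs <- unique(edges[, c("pre_type", "post_type")])
  pairs <- pairs[order(match(pairs$pre_type, DG_TYPES),
                       match(pairs$post_type, DG_TYPES)), , drop = FALSE]
  pops <- network$populations
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    pt <- pairs$pre_type[k]; qt <- pairs$post_type[k]
    e <- edges[edges$pre_type == pt & edges$post_type == qt, , drop = FALSE]
    post_cells <- pops$cell[pops$type == qt]
    conv <- tabulate(match(e$post, post_cells), nbins = length(post_cells))
    data.frame(
      pre_type = pt, post_type = qt, n_edges = nrow(e),
      divergence_mean = nrow(e) / cts[[pt]],
      convergence_mean = mean(conv),
      convergence_sd = stats::sd(conv),
      stringsAsFactors = FALSE
    )
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pre_type = character(0), post_type = character(0),
               n_edges = integer(0), divergence_mean = numeric(0),
               convergence_mean = numeric(0), convergence_sd = numeric(0))
  rownames(res) <- NULL
  res
}
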