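#' Construct a topographic connection rule
#'
#' One presynaptic-type to postsynaptic-type entry of the circuit's
#' connection table.  Each presynaptic cell makes exactly `divergence`
#' connections, drawn uniformly without replacement from a candidate pool of
#' the `pool_size` postsynaptic cells nearest to it on the septotemporal
#' axis, after removing the `center_exclusion` nearest cells (and the cell
#' itself for same-type rules, unless `allow_self`).
#'
#' @param pre,post Cell types (see [DG_TYPES]).
#' @param divergence Non-negative integer; connections per presynaptic cell.
#' @param pool_size Positive integer; size of the nearest-neighbour candidate
#'   pool.
#' @param center_exclusion Non-negative integer; number of nearest cells
#'   excluded from the pool (e.g. mossy-cell axons skip the 50 granule cells
#'   closest to the soma).
#' @param allow_self Logical; whether an autapse is permitted when `pre` and
#'   `post` are the same population (default `FALSE`).
#' @param synapse_ref Identifier of the synapse parameter set applied to the
#'   rule's edges; defaults to `"<pre>_<post>"`.
#' @return An object of class `dg_rule` (a named list).
#' @export
dg_rule <- function(pre, post, divergence, pool_size, center_exclusion = 0L,
                    allow_self = FALSE, synapse_ref = paste(pre, post, sep = "_")) {
  pre  <- match.arg(pre,  DG_TYPES)
  post <- match.arg(post, DG_TYPES)
  divergence <- as.integer(divergence)
  pool_size <- as.integer(pool_size)
  center_exclusion <- as.integer(center_exclusion)
  if (divergence < 0L) stop("divergence must be non-negative", call. = FALSE)
  if (pool_size < 1L) stop("pool_size must be positive", call. = FALSE)
  if (center_exclusion < 0L || center_exclusion >= pool_size) {
    stop("center_exclusion must satisfy 0 <= center_exclusion < pool_size",
         call. = FALSE)
  }
  if (divergence > pool_size - center_exclusion) {
    stop(sprintf("rule %s->%s infeasible: divergence %d exceeds pool %d - exclusion %d",
                 pre, post, divergence, pool_size, center_exclusion), call. = FALSE)
  }
  structure(
    list(pre = pre, post = post, divergence = divergence,
         pool_size = pool_size, center_exclusion = center_exclusion,
         allow_self = isTRUE(allow_self), synapse_ref = synapse_ref),
    class = "dg_rule"
  )
}

#' @export
print.dg_rule <- function(x, ...) {
  cat(sprintf("<dg_rule> %s -> %s  divergence %d, pool %d (excluding %d central)%s\n",
              x$pre, x$post, x$divergence, x$pool_size, x$center_exclusion,
              if (x$allow_self) ", autapses allowed" else ""))
  invisible(x)
}

#' Default connection rule set
#'
#' The circuit's connection table for the reduced 500/15/6/6 network.
#' Divergences and pools follow the topographic scheme of the underlying
#' dentate gyrus model: e.g. each mossy cell contacts 200 granule cells
#' chosen among the 350 nearest, excluding the 50 closest; each granule cell
#' contacts 1 mossy cell among its 3 nearest.  The healthy mode has no
#' GC-to-GC rule (granule cells are not directly connected in the intact
#' dentate gyrus) and basket cells do not project to HIPP cells.  The
#' granule-cell to HIPP divergence is 3, the value forced by the published
#' convergence of 250 HIPP inputs per cell at these population sizes (see
#' vignette).
#'
#' In `"pathological"` mode the same rules apply and recurrent GC-to-GC
#' "sprouted" connections are added separately by [generate_network()]
#' (mossy-fiber sprouting), optionally with mossy-cell deletion.
#'
#' @param mode `"healthy"` (default) or `"pathological"`; the rule list
#'   itself is identical, the mode is kept for interface symmetry.
#' @return List of [dg_rule] objects.
#' @export
default_rules <- function(mode = c("healthy", "pathological")) {
  mode <- match.arg(mode)
  list(
    dg_rule("GC", "MC", 1L, 3L),
    dg_rule("GC", "BC", 1L, 3L),
    dg_rule("GC", "HIPP", 3L, 5L),
    dg_rule("MC", "GC", 200L, 350L, center_exclusion = 50L),
    dg_rule("MC", "MC", 3L, 6L),
    dg_rule("MC", "BC", 1L, 3L, center_exclusion = 1L),
    dg_rule("MC", "HIPP", 2L, 5L),
    dg_rule("BC", "GC", 100L, 140L),
    dg_rule("BC", "MC", 3L, 7L),
    dg_rule("BC", "BC", 2L, 3L),
    dg_rule("HIPP", "GC", 160L, 260L),
    dg_rule("HIPP", "MC", 4L, 5L),
    dg_rule("HIPP", "BC", 4L, 5L)
  )
}

rule_label <- function(rule) paste(rule$pre, rule$post, sep = "->")

# Deterministic per-rule RNG substream: a small string hash folded into the
# base seed, kept within the 32-bit integer range so set.seed() accepts it.
# Adding or removing one rule never perturbs another rule's draws.
rule_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h + 1) %% 2147483647)
}
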