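#' Cell types of the reduced dentate gyrus circuit
#'
#' The four numerically dominant dentate gyrus cell classes retained by the
#' model: granule cells (GC, excitatory principal cells), mossy cells (MC,
#' excitatory hilar cells), basket cells (BC, perisomatic inhibitory
#' interneurons) and HIPP cells (hilar interneurons projecting to the
#' perforant-path termination zone).
#'
#' @format A character vector of length four.
#' @export
DG_TYPES <- c("GC", "MC", "BC", "HIPP")

#' Default population sizes
#'
#' The reduced-scale circuit: 500 granule cells, 15 mossy cells, 6 basket
#' cells and 6 HIPP cells (a roughly 2000:1 reduction of the rat dentate
#' gyrus).  The basket-cell count is 6, the value jointly consistent with the
#' model's convergence table (e.g. GC onto BC convergence 83.33 = 500/6);
#' see the package vignette for the reasoning.
#'
#' @return Named integer vector with elements `GC`, `MC`, `BC`, `HIPP`.
#' @export
default_counts <- function() {
  c(GC = 500L, MC = 15L, BC = 6L, HIPP = 6L)
}

#' Place cells on the septotemporal axis
#'
#' Assigns every cell of every population an evenly spaced, strictly
#' increasing position in `[0, 1]` along a single (septotemporal) axis:
#' cell `i` (0-based) of a population of `n` sits at `(i + 0.5) / n`.
#' Placement is deterministic; topographic connection rules measure
#' "nearness" on this axis.
#'
#' @param counts Named vector of positive cell counts; names must be the four
#'   types in [DG_TYPES] and all four must be present.
#' @return A data frame with one row per cell and columns `cell` (id,
#'   `"<TYPE><index>"` with 0-based index), `type` (factor), `index`
#'   (0-based integer within the population) and `pos` (axis position).
#'   The counts are attached as attribute `"counts"`.
#' @examples
#' pops <- place_cells(c(GC = 10, MC = 2, BC = 1, HIPP = 1))
#' subset(pops, type == "MC")$pos  # 0.25 0.75
#' @export
place_cells <- function(counts) {
  if (is.null(names(counts)) || !setequal(names(counts), DG_TYPES)) {
    stop("`counts` must be named with exactly the four types: ",
         paste(DG_TYPES, collapse = ", "), call. = FALSE)
  }
  counts <- counts[DG_TYPES]
  if (any(is.na(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("all population counts must be positive integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  names(counts) <- DG_TYPES
  rows <- lapply(DG_TYPES, function(tp) {
    n <- counts[[tp]]
    idx <- seq_len(n) - 1L
    data.frame(
      cell  = paste0(tp, idx),
      type  = factor(tp, levels = DG_TYPES),
      index = idx,
      pos   = (idx + 0.5) / n,
      stringsAsFactors = FALSE
    )
  })
  pops <- do.call(rbind, rows)
  rownames(pops) <- NULL
  attr(pops, "counts") <- counts
  pops
}

population_counts <- function(populations) {
  cts <- attr(populations, "counts")
  if (is.null(cts)) {
    tab <- table(populations$type)
    cts <- as.integer(tab[DG_TYPES])
    names(cts) <- DG_TYPES
  }
  cts
}
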