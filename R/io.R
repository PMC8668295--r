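#' Write / read a network edge list
#'
#' Tab-separated edge list with header `pre_id  post_id  pre_type
#' post_type`; cell ids are `"<TYPE><index>"` with 0-based indices.
#'
#' @param network A `dg_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "dg_network"))
  df <- network$edges[, c("pre", "post", "pre_type", "post_type")]
  names(df) <- c("pre_id", "post_id", "pre_type", "post_type")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param strict Require the four-column header and known cell types (used
#'   for files produced by [write_edge_list()]; plain two-column lists are
#'   accepted when `FALSE`).
#' @return `read_edge_list()`: data frame of edges.
#' @export
read_edge_list <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("malformed edge list %s: line %d has %d fields (expected %d)",
                 path, bad, ncols[bad], ncols[1]), call. = FALSE)
  }
  header <- parts[[1]]
  has_header <- identical(header[1:2], c("pre_id", "post_id")) ||
    identical(header[1:2], c("pre", "post"))
  body <- if (has_header) parts[-1] else parts
  if (!length(body)) stop("edge list has a header but no edges: ", path, call. = FALSE)
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- if (has_header) header else
    c("pre_id", "post_id", "pre_type", "post_type")[seq_len(ncols[1])]
  if (strict) {
    need <- c("pre_id", "post_id", "pre_type", "post_type")
    if (!all(need %in% names(df))) {
      stop("edge list lacks required columns: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    if (!all(df$pre_type %in% DG_TYPES) || !all(df$post_type %in% DG_TYPES)) {
      stop("edge list contains unknown cell types", call. = FALSE)
    }
  }
  df
}

#' Write network metadata
#'
#' JSON snapshot of a network's generation inputs: counts, mode, seed,
#' lesion settings and the consumed rule table.
#'
#' @param network A `dg_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_network_metadata <- function(network, path) {
  stopifnot(inherits(network, "dg_network"))
  meta <- list(
    counts = as.list(network$counts),
    mode = network$mode,
    seed = network$seed,
    sprouting_degree = network$sprouting_degree,
    mc_deleted = network$mc_deleted,
    rules = lapply(network$rules, function(r) {
      r[c("pre", "post", "divergence", "pool_size", "center_exclusion",
          "allow_self", "synapse_ref")]
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a network object from an edge list and metadata files
#'
#' Inverse of [write_edge_list()] + [write_network_metadata()]: reads the
#' files back into a `dg_network` that can be simulated or analyzed.
#' GC-to-GC edges are tagged with the sprouted synapse class.
#'
#' @param edge_file Edge-list TSV.
#' @param metadata_file Metadata JSON.
#' @return A `dg_network`.
#' @export
read_network <- function(edge_file, metadata_file) {
  if (!file.exists(metadata_file)) {
    stop("network metadata file not found: ", metadata_file, call. = FALSE)
  }
  meta <- jsonlite::read_json(metadata_file, simplifyVector = TRUE)
  counts <- unlist(meta$counts)
  populations <- place_cells(counts)
  e <- read_edge_list(edge_file, strict = TRUE)
  edges <- data.frame(
    pre = e$pre_id, post = e$post_id,
    pre_type = e$pre_type, post_type = e$post_type,
    synapse_ref = ifelse(e$pre_type == "GC" & e$post_type == "GC",
                         "GC_GC_sprouted",
                         paste(e$pre_type, e$post_type, sep = "_")),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(c(edges$pre, edges$post), populations$cell)
  if (length(unknown)) {
    stop("edge list refers to cells absent from the metadata populations: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  rules <- NULL
  if (!is.null(meta$rules)) {
    rl <- meta$rules
    rules <- lapply(seq_len(nrow(rl)), function(i) {
      dg_rule(rl$pre[i], rl$post[i], rl$divergence[i], rl$pool_size[i],
              rl$center_exclusion[i], rl$allow_self[i], rl$synapse_ref[i])
    })
  }
  structure(
    list(populations = populations, edges = edges, mode = meta$mode,
         seed = as.integer(meta$seed), counts = population_counts(populations),
         rules = rules,
         sprouting_degree = as.integer(meta$sprouting_degree %||% 0L),
         mc_deleted = as.character(meta$mc_deleted %||% character(0))),
    class = "dg_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration
#'
#' YAML (or JSON) configuration with sections `populations` (type: count),
#' `rules` (list of pre/post/divergence/pool_size/center_exclusion),
#' `mode`, `seed`, and optional `sprouting_degree` / `mc_loss`.  Missing
#' sections fall back to package defaults.
#'
#' @param path Configuration file.
#' @return List of arguments suitable for [generate_network()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  out$counts <- if (!is.null(cfg$populations)) unlist(cfg$populations) else default_counts()
  out$mode <- cfg$mode %||% "healthy"
  out$seed <- as.integer(cfg$seed %||% 1L)
  out$sprouting_degree <- as.integer(cfg$sprouting_degree %||% 2L)
  out$mc_loss <- as.integer(cfg$mc_loss %||% 0L)
  if (!is.null(cfg$rules)) {
    out$rules <- lapply(cfg$rules, function(r) {
      dg_rule(r$pre, r$post, r$divergence, r$pool_size,
              r$center_exclusion %||% 0L, isTRUE(r$allow_self),
              r$synapse_ref %||% paste(r$pre, r$post, sep = "_"))
    })
  } else {
    out$rules <- default_rules()
  }
  out
}

#' Write simulation outputs
#'
#' `write_raster()` writes the spike raster as TSV (`cell_id  time_ms`);
#' `write_traces()` writes the recorded membrane traces as CSV (`time_ms`
#' then one column per recorded compartment).
#'
#' @param sim A `dg_sim`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(sim, path) {
  stopifnot(inherits(sim, "dg_sim"))
  df <- data.frame(cell_id = sim$raster$cell, time_ms = sim$raster$time)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
write_traces <- function(sim, path) {
  stopifnot(inherits(sim, "dg_sim"))
  tr <- sim$traces
  names(tr)[1] <- "time_ms"
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON inventory of a run: seed, configuration snapshot, package version
#' and the output files with their MD5 checksums — enough to re-run the
#' pipeline bit-identically and verify its outputs.
#'
#' @param files Character vector of output paths.
#' @param seed Integer seed used.
#' @param config Arbitrary configuration list to snapshot.
#' @param path Manifest output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(files, seed, config, path) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("manifest refers to missing files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manifest <- list(
    artifact = paste0("dgnet ", as.character(utils::packageVersion("dgnet"))),
    seed = as.integer(seed),
    config = config,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
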