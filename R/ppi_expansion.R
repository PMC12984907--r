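#' @title Protein-protein interaction neighbor expansion
#' @name ppi_expansion
#' @description
#' Expands a risk-gene set to its immediate high-confidence interaction
#' neighbors (STRING-style combined score, conventional high-confidence band
#' at 700 on the 0-1000 scale), retaining for each neighbor the set of seed
#' risk genes it connects to. That provenance drives the later
#' direct/indirect classification of enriched drugs and the Sankey-style
#' reporting.
NULL

check_ppi_edges <- function(edges) {
  need <- c("gene_a", "gene_b", "combined_score")
  if (!is.data.frame(edges) || !all(need %in% names(edges))) {
    stop("`edges` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  s <- edges$combined_score
  if (anyNA(s) || any(s < 0) || any(s > 1000)) {
    stop("combined scores must lie in [0, 1000]", call. = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) {
    stop("self-edges (gene_a == gene_b) are not allowed", call. = FALSE)
  }
  invisible(edges)
}

#' Immediate high-confidence neighbors of a seed gene set
#'
#' For every undirected edge at or above the score cutoff with exactly one
#' endpoint in `seeds`, the other endpoint becomes a neighbor keyed to that
#' seed. Seeds never appear as neighbors (a seed adjacent to another seed is
#' already in the risk set). Seeds absent from the network contribute
#' nothing and are reported in the `missing_seeds` field.
#'
#' @param seeds character vector of risk-gene symbols (non-empty).
#' @param edges data.frame of undirected scored edges (`gene_a`, `gene_b`,
#'   `combined_score` on 0-1000).
#' @param min_score combined-score cutoff (default 700).
#' @param strict if `TRUE`, require `combined_score > min_score` instead of
#'   the default `>=` (the two differ only for edges scoring exactly
#'   `min_score`).
#' @param max_neighbors optional per-seed cap: keep only each seed's
#'   `max_neighbors` highest-scoring neighbors (default `Inf`, no cap).
#' @return object of class `neighbor_map`: list with `entries` (named list
#'   mapping neighbor to its seed character vector), `edge_table`
#'   (data.frame `neighbor`, `seed`, `combined_score_max`), `cutoff`,
#'   `strict` and `missing_seeds`.
#' @export
expand_neighbors <- function(seeds, edges, min_score = 700, strict = FALSE,
                             max_neighbors = Inf) {
  if (length(seeds) == 0L) stop("`seeds` must be non-empty", call. = FALSE)
  check_ppi_edges(edges)
  seeds <- unique(as.character(seeds))

  keep <- if (strict) edges$combined_score > min_score else
    edges$combined_score >= min_score
  e <- edges[keep, , drop = FALSE]

  a_seed <- e$gene_a %in% seeds
  b_seed <- e$gene_b %in% seeds
  # one endpoint a seed, the other not: orient as (seed, neighbor)
  fwd <- a_seed & !b_seed
  rev <- b_seed & !a_seed
  pairs <- data.frame(
    seed = c(e$gene_a[fwd], e$gene_b[rev]),
    neighbor = c(e$gene_b[fwd], e$gene_a[rev]),
    combined_score = c(e$combined_score[fwd], e$combined_score[rev]),
    stringsAsFactors = FALSE
  )
  # undirected duplicates: keep the best score per (seed, neighbor)
  if (nrow(pairs)) {
    key <- paste(pairs$seed, pairs$neighbor, sep = "\r")
    ord <- order(key, -pairs$combined_score)
    pairs <- pairs[ord, , drop = FALSE]
    pairs <- pairs[!duplicated(key[ord]), , drop = FALSE]
  }
  if (is.finite(max_neighbors) && nrow(pairs)) {
    keep_rows <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$seed),
                               function(i) {
      i[order(-pairs$combined_score[i])][seq_len(min(length(i), max_neighbors))]
    }), use.names = FALSE)
    pairs <- pairs[sort(keep_rows), , drop = FALSE]
  }

  present <- unique(c(edges$gene_a, edges$gene_b))
  missing_seeds <- setdiff(seeds, present)
  if (length(missing_seeds)) {
    message(length(missing_seeds), " seed(s) absent from the PPI network")
  }

  entries <- lapply(split(pairs$seed, pairs$neighbor),
                    function(s) sort(unique(s)))
  if (nrow(pairs)) {
    edge_table <- stats::aggregate(
      combined_score ~ neighbor + seed, data = pairs, FUN = max)
    names(edge_table)[names(edge_table) == "combined_score"] <-
      "combined_score_max"
  } else {
    edge_table <- data.frame(neighbor = character(0), seed = character(0),
                             combined_score_max = numeric(0))
  }
  structure(list(entries = entries, edge_table = edge_table,
                 cutoff = min_score, strict = strict,
                 missing_seeds = missing_seeds),
            class = "neighbor_map")
}

#' Neighbor symbols of a neighbor map
#' @param map a `neighbor_map` from [expand_neighbors()].
#' @return character vector of neighbor gene symbols.
#' @export
neighbor_genes <- function(map) {
  stopifnot(inherits(map, "neighbor_map"))
  names(map$entries)
}

#' @export
print.neighbor_map <- function(x, ...) {
  cat("Neighbor map:", length(x$entries), "neighbors of",
      length(unique(x$edge_table$seed)), "seeds at combined score",
      if (x$strict) ">" else ">=", x$cutoff, "\n")
  if (length(x$missing_seeds)) {
    cat("  seeds absent from network:", length(x$missing_seeds), "\n")
  }
  invisible(x)
}

#' Map protein identifiers in a PPI edge table to gene symbols
#'
#' STRING-style edge lists name proteins by database identifiers; this joins
#' a two-column alias table onto both endpoints, drops edges with an
#' unmappable endpoint (with a message), and collapses self-edges created by
#' aliasing.
#'
#' @param edges data.frame (`gene_a`, `gene_b`, `combined_score`) in protein
#'   identifier space.
#' @param aliases data.frame with columns `protein_id`, `symbol`.
#' @return edge data.frame in symbol space.
#' @export
map_ppi_aliases <- function(edges, aliases) {
  check_ppi_edges(edges)
  if (!all(c("protein_id", "symbol") %in% names(aliases))) {
    stop("`aliases` must have columns protein_id, symbol", call. = FALSE)
  }
  a <- aliases$symbol[match(edges$gene_a, aliases$protein_id)]
  b <- aliases$symbol[match(edges$gene_b, aliases$protein_id)]
  drop <- is.na(a) | is.na(b) | a == b
  if (any(drop)) {
    message(sum(drop), " edge(s) dropped during alias mapping")
  }
  data.frame(gene_a = a[!drop], gene_b = b[!drop],
             combined_score = edges$combined_score[!drop],
             stringsAsFactors = FALSE)
}
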