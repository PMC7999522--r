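#' Assemble the bait-centred interaction network
#'
#' Two edge types: `bioid` edges from the bait to every retained candidate,
#' weighted by the candidate's maximum biotinylation ratio across conditions
#' (the experimentally determined proximity evidence); and `known` edges taken
#' from a reference interaction table, added only between proteins already in
#' the network — the known-interaction layer annotates the candidate set, it
#' never expands it. Candidates without any known edge stay in the graph as
#' isolated spokes.
#'
#' @param candidates A `candidate_set` from [run_cascade()].
#' @param known A `known_edge_table` (already confidence-filtered on read) or
#'   `NULL` for a pure bait-spoke network.
#' @param min_confidence Additional inclusive confidence floor applied to
#'   `known` (default 0.5).
#' @return An `interaction_graph`: list with `nodes` (data frame `gene`,
#'   `candidate`, `max_ratio`) and `edges` (data frame `from`, `to`, `type`,
#'   `weight`), plus `bait`.
#' @export
build_network <- function(candidates, known = NULL, min_confidence = 0.5) {
  ret <- retained(candidates)
  if (nrow(ret) == 0) validation_error("cannot build a network from an empty candidate set")
  config <- attr(candidates, "config")
  bait <- config$bait_gene
  prey <- setdiff(toupper(ret$gene), bait)
  nodes <- data.frame(
    gene = c(bait, sort(prey)),
    candidate = c(bait %in% toupper(ret$gene), rep(TRUE, length(prey))),
    max_ratio = NA_real_, stringsAsFactors = FALSE
  )
  ratio_lookup <- stats::setNames(ret$max_ratio, toupper(ret$gene))
  nodes$max_ratio <- unname(ratio_lookup[nodes$gene])
  bioid_edges <- data.frame(
    from = rep(bait, length(prey)), to = sort(prey), type = "bioid",
    weight = unname(ratio_lookup[sort(prey)]), stringsAsFactors = FALSE
  )
  known_edges <- data.frame(from = character(0), to = character(0),
                            type = character(0), weight = numeric(0),
                            stringsAsFactors = FALSE)
  if (!is.null(known) && nrow(known) > 0) {
    keep <- known$confidence >= min_confidence &
      known$gene_a %in% nodes$gene & known$gene_b %in% nodes$gene
    k <- known[keep, , drop = FALSE]
    if (nrow(k) > 0)
      known_edges <- data.frame(from = k$gene_a, to = k$gene_b, type = "known",
                                weight = k$confidence, stringsAsFactors = FALSE)
  }
  edges <- rbind(bioid_edges, known_edges)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, bait = bait),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes (bait %s), %d bioid + %d known edges\n",
              nrow(x$nodes), x$bait,
              sum(x$edges$type == "bioid"), sum(x$edges$type == "known")))
  invisible(x)
}

#' Export a network as SIF plus attribute tables
#'
#' Writes the simple interaction format (source, edge type, target) consumed
#' by Cytoscape and other viewers, a node-attribute table (gene, candidate
#' flag, maximum ratio) and an edge-attribute table (endpoints, type,
#' weight/confidence). Nodes and edges are written in lexicographic order so
#' re-exporting the same graph reproduces identical bytes.
#'
#' @param graph An `interaction_graph`.
#' @param prefix Output path prefix: writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return Named character vector of the three paths, invisibly.
#' @export
export_graph <- function(graph, prefix) {
  edges <- graph$edges[order(graph$edges$type, graph$edges$from, graph$edges$to), ]
  nodes <- graph$nodes[order(graph$nodes$gene), ]
  sif_path <- paste0(prefix, ".sif")
  writeLines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to), sif_path)
  nodes_path <- paste0(prefix, "_nodes.tsv")
  write_delim_table(nodes, nodes_path, sep = "\t")
  edges_path <- paste0(prefix, "_edges.tsv")
  write_delim_table(edges, edges_path, sep = "\t")
  invisible(c(sif = sif_path, nodes = nodes_path, edges = edges_path))
}

#' Read a SIF file back into an edge data frame
#'
#' @param path SIF file (source, edge type, target; tab-delimited).
#' @return Data frame `from`, `type`, `to`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) format_error("SIF line %d does not have 3 fields", which(bad)[1])
  data.frame(
    from = vapply(parts, `[`, character(1), 1),
    type = vapply(parts, `[`, character(1), 2),
    to = vapply(parts, `[`, character(1), 3),
    stringsAsFactors = FALSE
  )
}
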