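# ---- annotated interaction networks ----

.type_rank <- c(bait = 0, T1 = 1, T2 = 2, T3 = 3, T4 = 4)

edge_style <- function(rank_a, rank_b) {
  worst <- pmax(rank_a, rank_b)
  ifelse(worst >= 4, "backslash", ifelse(worst >= 3, "dashed", "solid"))
}

opacity_band <- function(score) {
  ifelse(score >= 0.9, "high", ifelse(score >= 0.7, "mid", "low"))
}

#' Build the annotated AAPL interaction network
#'
#' Assembles the interaction graph around one bait: nodes are the bait,
#' every L1/L2 interactor, and those oxidized non-interactor ("grey")
#' proteins that share a known-interaction edge with the bait or an L1/L2
#' interactor. Edges are the known-interaction pairs with both endpoints
#' in the graph. Edge rendering attributes follow the interactor typing:
#' solid lines for edges among bait/T1/T2 nodes, dashed when a T3 protein
#' is involved, backslash for T4; the opacity band encodes the combined
#' score (>= 0.9 high, \[0.7, 0.9) mid, below low). Node fill is exported
#' as the numeric `epo_fc` attribute; rendering is the consumer's job.
#'
#' @param results Output of [classify_interactors()].
#' @param edges Normalized edge table (`protein_a`, `protein_b`,
#'   `combined_score` in \[0, 1\]).
#' @param bait_id Bait protein id.
#' @return An `igraph` graph with node attributes `level`, `epo_fc`,
#'   `string_type`, `is_bait` and edge attributes `combined_score`,
#'   `style`, `opacity_band`.
#' @export
build_network <- function(results, edges, bait_id) {
  assert_columns(results, c("protein_id", "level", "epo_fc", "string_type"),
                 "results")
  assert_columns(edges, c("protein_a", "protein_b", "combined_score"),
                 "edges")
  if (!is.character(bait_id) || length(bait_id) != 1L || !nzchar(bait_id)) {
    abort_aaplr("bait_id must be a single protein id", "aaplr_invalid_parameter")
  }
  interactors <- results$protein_id[results$level %in% c("L1", "L2")]
  core <- c(bait_id, interactors)
  grey_pool <- setdiff(results$protein_id, core)
  touches_core <- (edges$protein_a %in% core & edges$protein_b %in% grey_pool) |
                  (edges$protein_b %in% core & edges$protein_a %in% grey_pool)
  grey <- intersect(grey_pool,
                    unique(c(edges$protein_a[touches_core],
                             edges$protein_b[touches_core])))
  nodes <- data.frame(name = c(bait_id, setdiff(c(interactors, grey),
                                                bait_id)),
                      stringsAsFactors = FALSE)
  i <- match(nodes$name, results$protein_id)
  nodes$level <- ifelse(nodes$name == bait_id, "bait", results$level[i])
  nodes$epo_fc <- ifelse(nodes$name == bait_id, NA_real_, results$epo_fc[i])
  nodes$string_type <- ifelse(nodes$name == bait_id, "bait",
                              results$string_type[i])
  nodes$is_bait <- nodes$name == bait_id

  e <- edges[edges$protein_a %in% nodes$name &
             edges$protein_b %in% nodes$name, , drop = FALSE]
  if (nrow(e)) {
    ra <- .type_rank[nodes$string_type[match(e$protein_a, nodes$name)]]
    rb <- .type_rank[nodes$string_type[match(e$protein_b, nodes$name)]]
    e$style <- edge_style(ra, rb)
    e$opacity_band <- opacity_band(e$combined_score)
  } else {
    e$style <- character(0)
    e$opacity_band <- character(0)
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
}

#' Merge two single-bait networks
#'
#' Node union of two bait networks (the two-antigen overlay): shared nodes
#' carry both attribute sets (`level_a`/`level_b`, `epo_fc_a`/`epo_fc_b`)
#' and `shared = TRUE`; edges are unioned keeping the maximum combined
#' score on duplicates.
#'
#' @param graph_a,graph_b Graphs from [build_network()].
#' @return An undirected `igraph` graph with per-bait node attributes.
#' @export
merge_networks <- function(graph_a, graph_b) {
  va <- igraph::as_data_frame(graph_a, what = "vertices")
  vb <- igraph::as_data_frame(graph_b, what = "vertices")
  ea <- igraph::as_data_frame(graph_a, what = "edges")
  eb <- igraph::as_data_frame(graph_b, what = "edges")

  names_all <- union(va$name, vb$name)
  ia <- match(names_all, va$name)
  ib <- match(names_all, vb$name)
  nodes <- data.frame(
    name = names_all,
    level_a = ifelse(is.na(ia), NA_character_, va$level[ia]),
    level_b = ifelse(is.na(ib), NA_character_, vb$level[ib]),
    epo_fc_a = ifelse(is.na(ia), NA_real_, va$epo_fc[ia]),
    epo_fc_b = ifelse(is.na(ib), NA_real_, vb$epo_fc[ib]),
    is_bait = (!is.na(ia) & va$is_bait[ia]) | (!is.na(ib) & vb$is_bait[ib]),
    shared = !is.na(ia) & !is.na(ib),
    stringsAsFactors = FALSE
  )
  e <- rbind(ea[, c("from", "to", "combined_score", "style", "opacity_band")],
             eb[, c("from", "to", "combined_score", "style", "opacity_band")])
  if (nrow(e)) {
    key <- pair_key(e$from, e$to)
    e <- e[order(key, -e$combined_score), ]
    e <- e[!duplicated(pair_key(e$from, e$to)), ]
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
}

#' Write a network as GraphML
#'
#' @param graph An `igraph` graph.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path A `.graphml` file written by [write_network_graphml()].
#' @return An `igraph` graph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write a network as SIF plus node/edge attribute tables
#'
#' Cytoscape-friendly export: `<prefix>.sif` with `a interacts b` lines,
#' `<prefix>.nodes.tsv` and `<prefix>.edges.tsv` with the attributes.
#'
#' @param graph An `igraph` graph.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_network_sif <- function(graph, prefix) {
  e <- igraph::as_data_frame(graph, what = "edges")
  v <- igraph::as_data_frame(graph, what = "vertices")
  sif <- file.path(paste0(prefix, ".sif"))
  writeLines(if (nrow(e)) paste(e$from, "interacts", e$to) else character(0),
             sif)
  nodes_path <- paste0(prefix, ".nodes.tsv")
  edges_path <- paste0(prefix, ".edges.tsv")
  write.table(v, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(e, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, nodes_path, edges_path))
}
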