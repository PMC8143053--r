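# PPI prioritization: score-thresholded interaction graph, multi-source
# hop distances from the known disease-gene panel, and proximity filtering
# of integrated candidates ("shortest links" operationalized as hop
# distance <= 1, i.e. direct interactors, by default).

#' Build a protein-interaction graph from a weighted edge list
#'
#' Drops edges below the confidence threshold (0.4 mirrors the usual
#' medium-confidence convention), keeps the maximum score over duplicate
#' undirected edges, and retains requested query genes as isolated nodes
#' even when all their edges fall below the threshold.
#'
#' @param edges `data.frame(geneA, geneB, score)` (see [read_edge_list()]).
#' @param min_score minimum edge score retained.
#' @param keep_nodes gene symbols guaranteed to be present as nodes.
#' @return an undirected `igraph` graph with a `score` edge attribute.
#' @export
build_graph <- function(edges, min_score = 0.4, keep_nodes = NULL) {
  stopifnot(all(c("geneA", "geneB", "score") %in% names(edges)))
  edges <- edges[edges$geneA != edges$geneB, , drop = FALSE]
  a <- pmin(edges$geneA, edges$geneB); b <- pmax(edges$geneA, edges$geneB)
  key <- paste(a, b)
  o <- order(key, -edges$score)
  dedup <- !duplicated(key[o])
  edges <- data.frame(geneA = a[o][dedup], geneB = b[o][dedup],
                      score = edges$score[o][dedup], stringsAsFactors = FALSE)
  nodes <- unique(c(edges$geneA, edges$geneB, keep_nodes))
  edges <- edges[edges$score >= min_score, , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Multi-source hop distance from a known gene set
#'
#' Unweighted breadth-first hop counts from the nearest source; unreachable
#' nodes get `Inf`. Sources absent from the graph are skipped with a
#' message; an empty effective source set is a hard error.
#'
#' @param graph an `igraph` graph from [build_graph()].
#' @param sources character vector of source gene symbols.
#' @return named numeric vector of hop distances over all nodes.
#' @export
shortest_distances <- function(graph, sources) {
  present <- intersect(sources, igraph::V(graph)$name)
  absent <- setdiff(sources, present)
  if (length(absent)) {
    message(length(absent), " source gene(s) absent from the graph skipped")
  }
  if (!length(present)) {
    stop("no source gene is present in the graph", call. = FALSE)
  }
  d <- igraph::distances(graph, v = present, weights = NA)
  out <- apply(d, 2L, min)
  names(out) <- colnames(d)
  out
}

#' Prioritize candidates by network proximity to known disease genes
#'
#' Keeps candidate genes within `max_distance` hops of the known set and
#' emits the induced subnetwork over kept candidates plus known genes for
#' plotting. Candidates absent from the graph are excluded and reported in
#' the `not_in_graph` attribute.
#'
#' @param candidates `candidates` data.frame from [integrate_criteria()]
#'   (or any data.frame with a `gene` column; criterion flags are retained).
#' @param graph an `igraph` graph.
#' @param known character vector of known disease genes.
#' @param max_distance maximum hop distance kept (default 1 = direct
#'   interactor; `Inf` keeps every connected candidate).
#' @return list with `kept` (candidate rows + `distance` column) and
#'   `subnetwork` (`data.frame(geneA, geneB, score)` of the induced edges).
#' @export
prioritize_candidates <- function(candidates, graph, known,
                                  max_distance = 1) {
  stopifnot("gene" %in% names(candidates))
  dist <- shortest_distances(graph, known)
  in_graph <- candidates$gene %in% names(dist)
  missing <- candidates$gene[!in_graph]
  if (length(missing)) {
    message(length(missing), " candidate(s) absent from the graph excluded")
  }
  cand <- candidates[in_graph, , drop = FALSE]
  cand$distance <- dist[cand$gene]
  # unreachable candidates (infinite distance) are never kept, even at
  # max_distance = Inf, which keeps every connected candidate
  kept <- cand[is.finite(cand$distance) & cand$distance <= max_distance, ,
               drop = FALSE]
  rownames(kept) <- NULL
  sub_nodes <- union(kept$gene, intersect(known, igraph::V(graph)$name))
  sub <- igraph::induced_subgraph(graph, sub_nodes)
  el <- igraph::as_data_frame(sub, what = "edges")
  subnetwork <- data.frame(geneA = el$from, geneB = el$to,
                           score = el$score %||% rep(NA_real_, nrow(el)),
                           stringsAsFactors = FALSE)
  structure(list(kept = kept, subnetwork = subnetwork),
            not_in_graph = missing)
}
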