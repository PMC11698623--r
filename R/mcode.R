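# MCODE-style molecular complex detection on interaction graphs: k-core
# based vertex weighting, seeded complex growth with a vertex-weight
# percentage threshold, and optional haircut/fluff post-processing.

#' Filter interaction edges by confidence
#'
#' Keeps edges with confidence greater than or equal to
#' `min_confidence` (the conventional "high confidence 0.7" boundary is
#' inclusive); isolated nodes are retained.
#'
#' @param graph Undirected [igraph::graph], optionally with an edge
#'   attribute `confidence`.
#' @param min_confidence Minimum edge confidence (default 0.7).
#' @return The filtered graph, same vertex set.
#' @export
filter_edges <- function(graph, min_confidence = 0.7) {
  if (min_confidence <= 0) return(graph)
  conf <- igraph::edge_attr(graph, "confidence")
  if (is.null(conf))
    stopf("graph has no 'confidence' edge attribute")
  igraph::delete_edges(graph, igraph::E(graph)[conf < min_confidence])
}

#' MCODE vertex weights
#'
#' For each vertex the neighborhood graph (its neighbors, excluding the
#' vertex itself) is reduced to its highest k-core; the weight is the
#' core level k multiplied by the density of that core (the
#' core-clustering coefficient). Isolated vertices and vertices with an
#' edgeless neighborhood weigh 0.
#'
#' @param graph Undirected simple [igraph::graph].
#' @return Named numeric vector of vertex weights.
#' @export
mcode_vertex_weights <- function(graph) {
  ids <- igraph::V(graph)$name
  if (is.null(ids)) {
    ids <- as.character(seq_len(igraph::vcount(graph)))
    igraph::V(graph)$name <- ids
  }
  w <- vapply(ids, function(v) {
    nb <- igraph::neighbors(graph, v)
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(graph, nb)
    if (igraph::ecount(sub) == 0L) return(0)
    core <- igraph::coreness(sub)
    k <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == k))
    k * igraph::edge_density(core_sub)
  }, 0)
  names(w) <- ids
  w
}

# Density of a vertex subset within a graph; `loops = TRUE` uses the
# self-loop-allowing denominator n(n+1)/2.
subset_density <- function(graph, nodes, loops = FALSE) {
  n <- length(nodes)
  if (n < 2L) return(0)
  e <- igraph::ecount(igraph::induced_subgraph(graph, nodes))
  denom <- if (loops) n * (n + 1) / 2 else n * (n - 1) / 2
  e / denom
}

#' MCODE complex prediction
#'
#' Complexes are grown from unvisited seeds in decreasing weight order
#' (ties broken by vertex id). A breadth-first search admits a neighbor
#' when its weight is at least `(1 - node_score_cutoff)` times the
#' weight of the member that reached it, and the candidate is connected
#' to at least `min(complex size, 4)` current members (this support rule
#' stops complexes leaking across sparse bridges). Visited
#' vertices are excluded from later complexes, so complexes are
#' node-disjoint. The optional haircut iteratively removes members with
#' fewer than two in-complex neighbors; fluff adds unvisited neighbors
#' whose closed-neighborhood density exceeds `node_density_cutoff`
#' (fluffed vertices may appear in several complexes). Each complex is
#' scored as density times size and the result is sorted by score.
#'
#' @param graph Undirected simple [igraph::graph].
#' @param weights Vertex weights from [mcode_vertex_weights()];
#'   recomputed when `NULL`.
#' @param node_score_cutoff Admissible weight fraction below the seed
#'   weight (default 0.2).
#' @param node_density_cutoff Density threshold used by fluff
#'   (default 0).
#' @param haircut Remove weakly attached members (default `TRUE`).
#' @param fluff Add dense unvisited neighbors (default `FALSE`).
#' @param loops Use the self-loop density convention in complex scores
#'   (default `FALSE`).
#' @return Object of class `mcode_result`: list with `complexes` (list
#'   of vectors of node ids) and `summary` (data frame: complex, size,
#'   density, score), sorted by decreasing score.
#' @export
mcode_find_complexes <- function(graph, weights = NULL,
                                 node_score_cutoff = 0.2,
                                 node_density_cutoff = 0,
                                 haircut = TRUE, fluff = FALSE,
                                 loops = FALSE) {
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (is.null(weights)) weights <- mcode_vertex_weights(graph)
  ids <- igraph::V(graph)$name
  weights <- weights[ids]
  adj <- lapply(igraph::adjacent_vertices(graph, ids), function(v) v$name)
  names(adj) <- ids

  seed_order <- ids[order(-weights, ids)]
  visited <- new.env(parent = emptyenv())
  complexes <- list()

  for (seed in seed_order) {
    if (!is.null(visited[[seed]])) next
    if (weights[[seed]] <= 0) next
    members <- seed
    visited[[seed]] <- TRUE
    queue <- adj[[seed]]
    expander <- rep(weights[[seed]], length(queue))
    while (length(queue)) {
      w <- queue[[1L]]
      base <- expander[[1L]]
      queue <- queue[-1L]
      expander <- expander[-1L]
      if (!is.null(visited[[w]]) || w %in% members) next
      support <- sum(adj[[w]] %in% members)
      if (weights[[w]] >= (1 - node_score_cutoff) * base &&
          support >= min(length(members), 4L)) {
        members <- c(members, w)
        visited[[w]] <- TRUE
        queue <- c(queue, adj[[w]])
        expander <- c(expander, rep(weights[[w]], length(adj[[w]])))
      }
    }
    if (haircut) members <- haircut_members(members, adj)
    if (fluff && length(members)) {
      extra <- setdiff(unique(unlist(adj[members])), members)
      extra <- extra[vapply(extra, function(v) {
        subset_density(graph, c(v, adj[[v]])) > node_density_cutoff
      }, TRUE)]
      members <- c(members, sort(extra))
    }
    if (length(members) >= 2L)
      complexes <- c(complexes, list(sort(members)))
  }

  density <- vapply(complexes, function(m) subset_density(graph, m, loops), 0)
  score <- density * lengths(complexes)
  ord <- order(-score, -lengths(complexes),
               vapply(complexes, `[`, "", 1L))
  complexes <- complexes[ord]
  structure(list(
    complexes = complexes,
    summary = data.frame(complex = seq_along(complexes),
                         size = lengths(complexes),
                         density = density[ord], score = score[ord])),
    class = "mcode_result")
}

# Iteratively strip complex members with fewer than two in-complex
# neighbors.
haircut_members <- function(members, adj) {
  repeat {
    if (length(members) < 3L) return(character(0))
    deg <- vapply(members, function(v) sum(adj[[v]] %in% members), 0L)
    if (all(deg >= 2L)) return(members)
    members <- members[deg >= 2L]
  }
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("mcode_result: %d complex(es)\n", length(x$complexes)))
  if (nrow(x$summary)) print(head(x$summary, 10L))
  invisible(x)
}

#' One-call MCODE clustering of a confidence-weighted edge list
#'
#' Filters edges by confidence, computes vertex weights and predicts
#' complexes at the standard parameters.
#'
#' @param graph Undirected [igraph::graph] with a `confidence` edge
#'   attribute (or `min_confidence = 0` to skip filtering).
#' @param min_confidence Edge confidence cutoff (default 0.7).
#' @param ... Passed to [mcode_find_complexes()].
#' @return An `mcode_result`.
#' @export
mcode <- function(graph, min_confidence = 0.7, ...) {
  g <- if (min_confidence > 0) filter_edges(graph, min_confidence) else graph
  mcode_find_complexes(g, ...)
}
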