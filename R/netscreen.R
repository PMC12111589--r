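#' Intersect predicted compound targets with disease genes
#'
#' The union of all predicted targets is intersected with the disease gene
#' set; the per-compound target map is restricted to that shared set. Ids
#' are case-sensitive and whitespace-trimmed.
#'
#' @param compoundTargets named list, compound id -> character vector of
#'   target ids.
#' @param diseaseGenes character vector of disease-associated gene ids.
#' @return list with \code{shared} (sorted character) and \code{byCompound}
#'   (named list restricted to shared targets).
#' @export
intersectTargets <- function(compoundTargets, diseaseGenes) {
  compoundTargets <- lapply(compoundTargets, function(x) unique(trimws(x)))
  diseaseGenes <- unique(trimws(diseaseGenes))
  allT <- unique(unlist(compoundTargets, use.names = FALSE))
  shared <- sort(intersect(allT, diseaseGenes))
  list(shared = shared,
       byCompound = lapply(compoundTargets, function(x) sort(intersect(x, shared))))
}

#' Build a compound-target interaction graph
#'
#' Edges connect each compound to its disease-linked targets only, which is
#' what makes the downstream degree-greater-than-zero filter meaningful: a
#' compound with no disease-linked target is isolated.
#'
#' @param compoundTargets named list, compound -> targets.
#' @param diseaseGenes disease gene ids; targets outside this set are dropped.
#' @return list with \code{edges} (data.frame from, to), \code{nodes}
#'   (data.frame node, kind in compound/target).
#' @export
compoundTargetGraph <- function(compoundTargets, diseaseGenes) {
  it <- intersectTargets(compoundTargets, diseaseGenes)
  from <- rep(names(it$byCompound), lengths(it$byCompound))
  to <- unlist(it$byCompound, use.names = FALSE)
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(
    node = c(names(compoundTargets), it$shared),
    kind = c(rep("compound", length(compoundTargets)),
             rep("target", length(it$shared))),
    stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes)
}

#' Topology metrics of an undirected network
#'
#' Degree (incident edge count), unnormalized shortest-path betweenness
#' (endpoints excluded, summed over unordered pairs) and connected-component
#' closeness \eqn{(r - 1) / \sum d}, where r is the number of nodes reachable
#' from the node and the sum runs over their distances. Isolated nodes get
#' closeness 0 by convention.
#'
#' @param edges data.frame with two character columns (from, to); self-loops
#'   and duplicate edges are rejected.
#' @param nodes optional character vector of node ids (to include isolated
#'   nodes not present in any edge).
#' @return data.frame(node, degree, betweenness, closeness).
#' @export
topologyMetrics <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges)) {
    a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
    if (any(a == b)) stop("self-loops are not allowed")
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  }
  ids <- unique(c(if (nrow(edges)) c(as.character(edges[[1]]),
                                     as.character(edges[[2]])), nodes))
  if (!length(ids))
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric()))
  g <- igraph::graph_from_data_frame(
    edges[, 1:2, drop = FALSE], directed = FALSE,
    vertices = data.frame(name = ids))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  # component-restricted closeness: (reachable - 1) / sum(distances)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) 0 else length(di) / sum(di)
  }, numeric(1))
  data.frame(node = ids, degree = as.integer(deg[ids]),
             betweenness = as.numeric(btw[ids]), closeness = clo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter candidate compounds by network degree
#'
#' Keeps compounds with degree strictly greater than zero, ordered by degree
#' descending then id ascending, each row carrying its topology metrics.
#'
#' @param metrics data.frame from \code{\link{topologyMetrics}}.
#' @param compoundIds ids of the compound nodes to consider; every id must
#'   be present in \code{metrics}.
#' @return data.frame subset of \code{metrics}, ordered.
#' @export
filterCandidates <- function(metrics, compoundIds) {
  unknown <- setdiff(compoundIds, metrics$node)
  if (length(unknown))
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  m <- metrics[metrics$node %in% compoundIds & metrics$degree > 0, , drop = FALSE]
  m <- m[order(-m$degree, m$node), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Network-topology candidate screen
#'
#' Convenience wrapper: intersect targets with disease genes, build the
#' compound-target graph, compute topology metrics, and keep compounds with
#' degree > 0.
#'
#' @inheritParams compoundTargetGraph
#' @return list with \code{shared} targets, \code{metrics} for all nodes and
#'   \code{candidates} (the filtered, ordered compound rows).
#' @export
networkScreen <- function(compoundTargets, diseaseGenes) {
  gr <- compoundTargetGraph(compoundTargets, diseaseGenes)
  it <- intersectTargets(compoundTargets, diseaseGenes)
  metrics <- topologyMetrics(gr$edges, nodes = gr$nodes$node)
  cand <- filterCandidates(metrics, names(compoundTargets))
  list(shared = it$shared, metrics = metrics, candidates = cand)
}
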