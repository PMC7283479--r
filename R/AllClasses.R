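#' @import methods
NULL

#' Weighted bipartite tick-host network
#'
#' Two-mode graph of tick species/stage nodes against host-genus nodes.
#' Tick nodes are keyed `"Genus_species|stage"`, host nodes by genus. Edges
#' carry the aggregated number of literature records of that tick stage on
#' that host genus. Edges only ever connect a tick node to a host node;
#' isolated nodes are permitted (they arise in intra-cluster subnetworks).
#'
#' @slot edges data.frame with columns `tick`, `host`, `weight` (> 0),
#'   one row per distinct tick-host pair.
#' @slot tickNodes character vector of tick `species|stage` identifiers.
#' @slot hostNodes character vector of host genus identifiers.
#'
#' @seealso [buildNetwork()], [tickNodes()], [hostNodes()], [edgeTable()],
#'   [incidenceMatrix()], [asIgraph()]
#' @export
setClass("BipartiteNetwork",
  slots = c(edges = "data.frame", tickNodes = "character",
            hostNodes = "character"))

setValidity("BipartiteNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!all(c("tick", "host", "weight") %in% names(e)))
    return("edges must have columns 'tick', 'host', 'weight'")
  if (nrow(e)) {
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      msgs <- c(msgs, "edge weights must be finite and > 0")
    if (anyDuplicated(paste(e$tick, e$host, sep = "\r")))
      msgs <- c(msgs, "duplicate tick-host edges are not allowed")
    if (!all(e$tick %in% object@tickNodes))
      msgs <- c(msgs, "edge tick endpoints missing from tickNodes")
    if (!all(e$host %in% object@hostNodes))
      msgs <- c(msgs, "edge host endpoints missing from hostNodes")
  }
  if (anyDuplicated(object@tickNodes) || anyDuplicated(object@hostNodes))
    msgs <- c(msgs, "node identifiers must be unique")
  if (length(intersect(object@tickNodes, object@hostNodes)))
    msgs <- c(msgs, "a node cannot belong to both modes")
  if (length(msgs)) msgs else TRUE
})

#' Community partition of a bipartite network
#'
#' Node-to-cluster assignment together with its weighted Newman-Girvan
#' modularity. Cluster ids are consecutive integers relabelled by
#' descending cluster size so that reports are stable across runs.
#'
#' @slot membership named integer vector, node id -> cluster id.
#' @slot modularity modularity Q of the assignment (resolution-1 score,
#'   as returned by [modularityScore()]).
#' @slot resolution resolution parameter used by the Louvain run.
#' @slot seed integer seed of the winning restart.
#' @slot nRestarts number of Louvain restarts explored.
#'
#' @seealso [louvainPartition()], [clusterAssignments()], [modularityQ()]
#' @export
setClass("NetworkPartition",
  slots = c(membership = "integer", modularity = "numeric",
            resolution = "numeric", seed = "integer", nRestarts = "integer"))

setValidity("NetworkPartition", function(object) {
  m <- object@membership
  msgs <- character()
  if (length(m) && is.null(names(m)))
    msgs <- c(msgs, "membership must be named by node id")
  if (anyNA(m)) msgs <- c(msgs, "membership may not contain NA")
  if (length(object@modularity) != 1 || object@modularity < -0.5 ||
      object@modularity > 1 + 1e-12)
    msgs <- c(msgs, "modularity must be a single value in [-0.5, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BipartiteNetwork number of nodes (both modes)
#' @param x,object a `BipartiteNetwork`
#' @export
setMethod("length", "BipartiteNetwork", function(x)
  length(x@tickNodes) + length(x@hostNodes))

setMethod("show", "BipartiteNetwork", function(object) {
  cat("BipartiteNetwork:", length(object@tickNodes), "tick species/stage nodes,",
      length(object@hostNodes), "host genera,", nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  total record weight:", sum(object@edges$weight), "\n")
})

setMethod("show", "NetworkPartition", function(object) {
  k <- length(unique(object@membership))
  cat("NetworkPartition:", k, "clusters over", length(object@membership),
      "nodes; Q =", format(object@modularity, digits = 4),
      "(resolution", object@resolution, ")\n")
})

#' Accessors for network and partition objects
#'
#' @param x a [BipartiteNetwork-class] or [NetworkPartition-class]
#' @return `tickNodes`/`hostNodes`: character vectors of node ids;
#'   `edgeTable`: data.frame of edges; `incidenceMatrix`: numeric
#'   ticks-by-hosts weight matrix; `clusterAssignments`: named integer
#'   vector node -> cluster; `modularityQ`: numeric Q.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tickNodes", function(x) standardGeneric("tickNodes"))
#' @rdname accessors
#' @export
setGeneric("hostNodes", function(x) standardGeneric("hostNodes"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("incidenceMatrix", function(x) standardGeneric("incidenceMatrix"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))

#' @rdname accessors
setMethod("tickNodes", "BipartiteNetwork", function(x) x@tickNodes)
#' @rdname accessors
setMethod("hostNodes", "BipartiteNetwork", function(x) x@hostNodes)
#' @rdname accessors
setMethod("edgeTable", "BipartiteNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("incidenceMatrix", "BipartiteNetwork", function(x) {
  m <- matrix(0, length(x@tickNodes), length(x@hostNodes),
              dimnames = list(x@tickNodes, x@hostNodes))
  if (nrow(x@edges))
    m[cbind(match(x@edges$tick, x@tickNodes),
            match(x@edges$host, x@hostNodes))] <- x@edges$weight
  m
})

#' @rdname accessors
setMethod("asIgraph", "BipartiteNetwork", function(x) {
  nodes <- c(x@tickNodes, x@hostNodes)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "type",
    value = nodes %in% x@hostNodes)  # TRUE = host mode
  g <- igraph::set_vertex_attr(g, "mode",
    value = ifelse(nodes %in% x@hostNodes, "host", "tick"))
  if (nrow(x@edges)) {
    ev <- rbind(match(x@edges$tick, nodes), match(x@edges$host, nodes))
    g <- igraph::add_edges(g, as.vector(ev))
    g <- igraph::set_edge_attr(g, "weight", value = x@edges$weight)
  }
  g
})

#' @rdname accessors
setMethod("clusterAssignments", "NetworkPartition", function(x) x@membership)
#' @rdname accessors
setMethod("modularityQ", "NetworkPartition", function(x) x@modularity)

# internal constructor: tolerates isolated nodes, enforces validity
newBipartiteNetwork <- function(edges, tickNodes, hostNodes) {
  rownames(edges) <- NULL
  methods::new("BipartiteNetwork",
               edges = edges[, c("tick", "host", "weight")],
               tickNodes = as.character(tickNodes),
               hostNodes = as.character(hostNodes))
}
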