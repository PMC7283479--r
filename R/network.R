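#' Build the weighted bipartite tick-host network
#'
#' One tick node per species|stage, one host node per genus; edge weight
#' is the aggregated pair weight. The graph is treated as undirected by
#' every downstream algorithm.
#'
#' @param pairs data.frame from [expandPairs()] with columns
#'   `tick_node_id`, `host_genus`, `weight`.
#' @return a [BipartiteNetwork-class].
#' @export
buildNetwork <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs))
    stop("cannot build a network from an empty pair set")
  need <- c("tick_node_id", "host_genus", "weight")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(pairs$tick_node_id, pairs$host_genus, sep = "\r")))
    stop("duplicate (tick_node_id, host_genus) pairs; aggregate first with expandPairs()")
  splitTickNodeId(unique(pairs$tick_node_id))  # validates the id format
  edges <- data.frame(tick = pairs$tick_node_id, host = pairs$host_genus,
                      weight = as.numeric(pairs$weight),
                      stringsAsFactors = FALSE)
  newBipartiteNetwork(edges,
                      tickNodes = sort(unique(edges$tick)),
                      hostNodes = sort(unique(edges$host)))
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' Q = sum over clusters c of \[ w_c / W - (s_c / 2W)^2 \], with W the
#' total edge weight, w_c the intra-cluster edge weight and s_c the sum
#' of node strengths in c. The two-mode graph is scored as a unipartite
#' weighted graph, matching how Gephi's Louvain treats bipartite data.
#'
#' @param net a [BipartiteNetwork-class].
#' @param assignment named integer/numeric vector, node id -> cluster, or
#'   a [NetworkPartition-class].
#' @return modularity Q.
#' @export
modularityScore <- function(net, assignment) {
  if (methods::is(assignment, "NetworkPartition"))
    assignment <- clusterAssignments(assignment)
  nodes <- c(tickNodes(net), hostNodes(net))
  missing <- setdiff(nodes, names(assignment))
  if (length(missing))
    stop("nodes missing from assignment: ", paste(missing, collapse = ", "))
  e <- edgeTable(net)
  W <- sum(e$weight)
  if (W == 0) stop("network has no edges")
  ct <- assignment[e$tick]; ch <- assignment[e$host]
  wIntra <- tapply(e$weight[ct == ch], ct[ct == ch], sum)
  strength <- tapply(c(e$weight, e$weight), assignment[c(e$tick, e$host)], sum)
  sum(wIntra) / W - sum((strength / (2 * W))^2)
}

#' Louvain community detection on the two-mode graph
#'
#' Runs weighted Louvain (igraph's multilevel implementation) on the
#' bipartite graph treated as unipartite, with seeded restarts; the
#' best-modularity partition is kept and its seed recorded. Cluster ids
#' are relabelled 1..k by descending cluster size (ties by smallest node
#' id) so that reports are stable.
#'
#' @param net a [BipartiteNetwork-class].
#' @param resolution Louvain resolution (1 = classic modularity).
#' @param seed integer; restart r uses seed `seed + r - 1`.
#' @param nRestarts number of restarts (>= 1).
#' @param weighted use edge weights (`TRUE`, default) or the binary graph.
#' @return a [NetworkPartition-class].
#' @export
louvainPartition <- function(net, resolution = 1, seed = 1L, nRestarts = 1L,
                             weighted = TRUE) {
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0) stop("cannot partition a network with no edges")
  w <- if (weighted) igraph::E(g)$weight else NA
  best <- NULL; bestQ <- -Inf; bestSeed <- NA_integer_
  for (r in seq_len(max(1L, nRestarts))) {
    s <- as.integer(seed) + r - 1L
    set.seed(s)
    cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
    memb <- igraph::membership(cl)
    q <- modularityScore(net, memb)
    if (q > bestQ + 1e-12) { best <- memb; bestQ <- q; bestSeed <- s }
  }
  memb <- relabelBySize(best)
  methods::new("NetworkPartition", membership = memb,
               modularity = modularityScore(net, memb),
               resolution = as.numeric(resolution),
               seed = bestSeed, nRestarts = as.integer(max(1L, nRestarts)))
}

relabelBySize <- function(memb) {
  memb <- structure(as.integer(memb), names = names(memb))
  sizes <- table(memb)
  anchor <- tapply(names(memb), memb, min)        # tie-break: smallest node id
  ord <- order(-as.integer(sizes), anchor[names(sizes)])
  newId <- integer(length(sizes))
  newId[as.integer(names(sizes))[ord]] <- seq_along(ord)
  structure(newId[memb], names = names(memb))
}

#' Detect life-stage cluster switching
#'
#' Groups the partitioned tick nodes by species (splitting the
#' `species|stage` key) and flags the species whose stages fall in
#' different clusters -- ticks that change their host community along the
#' life cycle. Also tallies switching per tick genus.
#'
#' @param partition a [NetworkPartition-class] computed on the full network.
#' @param tickNodeIds character vector of tick node ids to analyse
#'   (typically `tickNodes(net)`).
#' @return list with `perStage` (species, stage, cluster), `species`
#'   (species, n_stages, n_distinct_clusters, switches, stage->cluster
#'   map as text) and `genus` (genus, n_species, n_switching).
#' @export
detectClusterSwitch <- function(partition, tickNodeIds) {
  memb <- clusterAssignments(partition)
  missing <- setdiff(tickNodeIds, names(memb))
  if (length(missing))
    stop("tick nodes missing from partition: ", paste(missing, collapse = ", "))
  info <- splitTickNodeId(tickNodeIds)
  info$cluster <- unname(memb[info$node])
  info <- info[order(info$species, match(info$stage, RECORD_STAGES)), ]
  perSpecies <- do.call(rbind, lapply(split(info, info$species), function(d) {
    data.frame(species = d$species[1], n_stages = nrow(d),
               n_distinct_clusters = length(unique(d$cluster)),
               switches = length(unique(d$cluster)) >= 2L,
               stage_map = paste(paste0(substr(d$stage, 1, 1), ":",
                                        d$cluster), collapse = " "),
               stringsAsFactors = FALSE)
  }))
  rownames(perSpecies) <- NULL
  gsum <- do.call(rbind, lapply(split(perSpecies, sub("_.*", "",
                                                      perSpecies$species)),
    function(d) data.frame(genus = sub("_.*", "", d$species[1]),
                           n_species = nrow(d),
                           n_switching = sum(d$switches),
                           stringsAsFactors = FALSE)))
  rownames(gsum) <- NULL
  list(perStage = info[, c("species", "stage", "cluster")],
       species = perSpecies, genus = gsum)
}

#' NODF nestedness of the network (0-100)
#'
#' Binarizes the incidence matrix and computes NODF (nestedness by
#' overlap and decreasing fill, averaged over row and column pairs) via
#' \code{vegan::nestednodf}; 100 = perfectly nested, 0 = no nested
#' structure.
#'
#' @param net a [BipartiteNetwork-class].
#' @return NODF in \[0, 100\].
#' @export
nestednessIndex <- function(net) {
  m <- incidenceMatrix(net) > 0
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("NODF needs at least 2 tick nodes and 2 host nodes")
  unname(vegan::nestednodf(m * 1)$statistic["NODF"])
}

#' Extract a cluster's subnetwork
#'
#' Mode (i), `includeExternal = FALSE`: the cluster's nodes and only the
#' intra-cluster edges. Mode (ii), `includeExternal = TRUE`: the cluster's
#' nodes plus every edge incident to them, which brings their external
#' partner nodes into the subnetwork. Comparing cluster indices between
#' the two configurations quantifies what the inter-cluster links
#' contribute.
#'
#' @param net a [BipartiteNetwork-class].
#' @param partition a [NetworkPartition-class].
#' @param clusterId cluster to extract.
#' @param includeExternal include edges to other clusters (mode ii).
#' @return a [BipartiteNetwork-class]; members without surviving edges are
#'   kept as isolated nodes.
#' @export
extractClusterSubnetwork <- function(net, partition, clusterId,
                                     includeExternal = FALSE) {
  memb <- clusterAssignments(partition)
  if (!clusterId %in% memb) stop("unknown cluster id: ", clusterId)
  members <- names(memb)[memb == clusterId]
  e <- edgeTable(net)
  keep <- if (includeExternal) e$tick %in% members | e$host %in% members
          else e$tick %in% members & e$host %in% members
  e <- e[keep, , drop = FALSE]
  ticks <- sort(unique(c(intersect(members, tickNodes(net)), e$tick)))
  hosts <- sort(unique(c(intersect(members, hostNodes(net)), e$host)))
  newBipartiteNetwork(e, ticks, hosts)
}

#' Export the network as GraphML
#'
#' Node attributes: `mode` (tick/host), `cluster` (if a partition is
#' given), `species`/`stage` for tick nodes; edge attribute `weight`.
#'
#' @param net a [BipartiteNetwork-class].
#' @param path output file.
#' @param partition optional [NetworkPartition-class].
#' @export
exportGraphML <- function(net, path, partition = NULL) {
  g <- annotatedGraph(net, partition)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export the network as GEXF 1.2
#'
#' Minimal GEXF emitter (undirected, weighted, with `mode` and `cluster`
#' node attributes) for interoperability with Gephi-style tools.
#'
#' @inheritParams exportGraphML
#' @export
exportGEXF <- function(net, path, partition = NULL) {
  xmlq <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  nodes <- c(tickNodes(net), hostNodes(net))
  mode <- ifelse(nodes %in% hostNodes(net), "host", "tick")
  cl <- if (!is.null(partition))
    unname(clusterAssignments(partition)[nodes]) else rep(NA_integer_,
                                                          length(nodes))
  e <- edgeTable(net)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="mode" type="string"/>',
    '      <attribute id="1" title="cluster" type="integer"/>',
    '    </attributes>',
    '    <nodes>',
    sprintf('      <node id="%s" label="%s"><attvalues><attvalue for="0" value="%s"/>%s</attvalues></node>',
            xmlq(nodes), xmlq(nodes), mode,
            ifelse(is.na(cl), "",
                   sprintf('<attvalue for="1" value="%d"/>', cl))),
    '    </nodes>',
    '    <edges>',
    if (nrow(e)) sprintf('      <edge id="%d" source="%s" target="%s" weight="%g"/>',
                         seq_len(nrow(e)) - 1L, xmlq(e$tick), xmlq(e$host),
                         e$weight) else character(),
    '    </edges>',
    '  </graph>',
    '</gexf>')
  writeLines(lines, path)
  invisible(path)
}

annotatedGraph <- function(net, partition = NULL) {
  g <- asIgraph(net)
  nodes <- igraph::V(g)$name
  isTick <- nodes %in% tickNodes(net)
  sp <- rep(NA_character_, length(nodes)); st <- sp
  if (any(isTick)) {
    info <- splitTickNodeId(nodes[isTick])
    sp[isTick] <- info$species; st[isTick] <- info$stage
  }
  g <- igraph::set_vertex_attr(g, "species", value = sp)
  g <- igraph::set_vertex_attr(g, "stage", value = st)
  if (!is.null(partition))
    g <- igraph::set_vertex_attr(g, "cluster",
      value = unname(clusterAssignments(partition)[nodes]))
  g
}
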