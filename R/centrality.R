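#' Betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness (Brandes) on the undirected
#' two-mode graph; contributions of a node pair are split equally among
#' its equal-length shortest paths. Geodesics are unweighted by default;
#' with `weighted = TRUE` edge distance is 1/weight (strong associations
#' are short). The display scaling log(BNC + 1) x 10 (natural log) avoids
#' zeros and compresses the heavy right tail.
#'
#' @param net a [BipartiteNetwork-class].
#' @param weighted use 1/weight edge distances for geodesics.
#' @param partition optional [NetworkPartition-class]; adds a `cluster`
#'   column.
#' @return data.frame: `node_id`, `mode`, `cluster`, `bnc`, `scaled_bnc`.
#' @export
betweennessTable <- function(net, weighted = FALSE, partition = NULL) {
  g <- asIgraph(net)
  if (igraph::vcount(g) == 0) stop("network is empty")
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  b <- igraph::betweenness(g, directed = FALSE, weights = w, normalized = FALSE)
  nodes <- igraph::V(g)$name
  out <- data.frame(node_id = nodes,
                    mode = ifelse(nodes %in% hostNodes(net), "host", "tick"),
                    cluster = if (!is.null(partition))
                      unname(clusterAssignments(partition)[nodes])
                    else NA_integer_,
                    bnc = unname(b),
                    scaled_bnc = log(unname(b) + 1) * 10,
                    stringsAsFactors = FALSE)
  attr(out, "log_base") <- "natural"
  rownames(out) <- NULL
  out
}

#' Mean betweenness of tick nodes per cluster
#'
#' Arithmetic mean of raw BNC over the tick nodes of each cluster; a
#' cluster without tick nodes is reported with `NA` (mean undefined).
#'
#' @param table output of [betweennessTable()].
#' @param partition a [NetworkPartition-class].
#' @return data.frame `cluster`, `n_ticks`, `mean_bnc`.
#' @export
clusterMeanBNC <- function(table, partition) {
  memb <- clusterAssignments(partition)
  missing <- setdiff(table$node_id, names(memb))
  if (length(missing))
    stop("nodes missing from partition: ", paste(missing, collapse = ", "))
  clusters <- sort(unique(memb))
  ticks <- table[table$mode == "tick", , drop = FALSE]
  tickCl <- unname(memb[ticks$node_id])
  out <- data.frame(cluster = clusters,
    n_ticks = vapply(clusters, function(k) sum(tickCl == k), 1L),
    mean_bnc = vapply(clusters, function(k) {
      v <- ticks$bnc[tickCl == k]
      if (length(v)) mean(v) else NA_real_
    }, 1.0))
  rownames(out) <- NULL
  out
}

#' Relation between centrality and phylogenetic host specificity
#'
#' Spearman rank correlation of the log-scaled BNC of each tick
#' species/stage against its MPD standardized effect size (Z). A negative
#' correlation means that ticks whose hosts are phylogenetically
#' clustered (low MPD, negative Z) tend to occupy central positions in
#' the network.
#'
#' @param table output of [betweennessTable()].
#' @param phyloResults output of [batchSpecificity()] keyed by the same
#'   species|stage unit ids.
#' @return list: `rho`, `p_value`, `n`, `method`, and `reason` when the
#'   correlation is undefined (zero variance).
#' @export
bncMpdRelation <- function(table, phyloResults) {
  joint <- merge(table[table$mode == "tick", c("node_id", "scaled_bnc")],
                 phyloResults[, c("unit_id", "Z")],
                 by.x = "node_id", by.y = "unit_id")
  joint <- joint[stats::complete.cases(joint), , drop = FALSE]
  if (nrow(joint) < 3)
    stop("fewer than 3 joint (BNC, Z) observations")
  if (stats::sd(joint$Z) == 0 || stats::sd(joint$scaled_bnc) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(joint),
                method = "spearman", reason = "zero variance in one variable"))
  ct <- suppressWarnings(stats::cor.test(joint$scaled_bnc, joint$Z,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(joint),
       method = "spearman", reason = NA_character_)
}
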