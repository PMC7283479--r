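toyPairs <- function() data.frame(
  tick_node_id = c("Amblyomma_a|larva", "Amblyomma_a|larva", "Ixodes_b|adult"),
  host_genus = c("Rattus", "Mazama", "Rattus"),
  weight = c(2, 1, 3))

test_that("network construction gives one node per id and one edge per pair", {
  net <- buildNetwork(toyPairs())
  expect_s4_class(net, "BipartiteNetwork")
  expect_equal(length(tickNodes(net)), 2)
  expect_equal(length(hostNodes(net)), 2)
  expect_equal(nrow(edgeTable(net)), 3)
  expect_equal(sum(incidenceMatrix(net)), 6)
  expect_error(buildNetwork(toyPairs()[0, ]), "empty")
  expect_error(buildNetwork(rbind(toyPairs(), toyPairs()[1, ])), "duplicate")
  expect_error(buildNetwork(data.frame(tick_node_id = "Amblyomma_a",
                                       host_genus = "Rattus", weight = 1)),
               "malformed")
})

test_that("modularity matches hand computation and the matrix formula", {
  # two disconnected unweighted 'triangles' (bipartite 6-cycles are the
  # two-mode analogue; use two disjoint K22-style blocks with known Q)
  pairs <- data.frame(
    tick_node_id = rep(c("Aa_a|larva", "Bb_b|larva", "Cc_c|larva",
                         "Dd_d|adult"), each = 2),
    host_genus = c("G1", "G2", "G1", "G2", "G3", "G4", "G3", "G4"),
    weight = 1)
  net <- buildNetwork(pairs)
  comp <- c(Aa_a.larva = 1, Bb_b.larva = 1, Cc_c.larva = 2, Dd_d.adult = 2,
            G1 = 1, G2 = 1, G3 = 2, G4 = 2)
  names(comp) <- c("Aa_a|larva", "Bb_b|larva", "Cc_c|larva", "Dd_d|adult",
                   "G1", "G2", "G3", "G4")
  # each component holds half the weight and half the strength:
  # Q = 2 * (1/2 - (1/2)^2) = 0.5
  expect_equal(modularityScore(net, comp), 0.5)
  # all-in-one partition always scores 0
  one <- comp; one[] <- 1
  expect_equal(modularityScore(net, one), 0)
  # node missing from assignment is named
  expect_error(modularityScore(net, comp[-1]), "Aa_a")
  # agreement with the independent modularity-matrix formula
  for (seed in 1:10) {
    net2 <- randomBipartite(4, 4, seed = seed)
    nodes <- c(tickNodes(net2), hostNodes(net2))
    set.seed(seed)
    code <- sample(1:3, length(nodes), replace = TRUE)
    names(code) <- nodes
    expect_equal(modularityScore(net2, code),
                 qFromModularityMatrix(adjacencyOf(net2), unname(code)))
  }
})

test_that("louvain separates disconnected components and is reproducible", {
  pairs <- data.frame(
    tick_node_id = rep(c("Aa_a|larva", "Bb_b|larva", "Cc_c|larva",
                         "Dd_d|adult"), each = 2),
    host_genus = c("G1", "G2", "G1", "G2", "G3", "G4", "G3", "G4"),
    weight = 1)
  net <- buildNetwork(pairs)
  part <- louvainPartition(net, seed = 3)
  memb <- clusterAssignments(part)
  expect_equal(length(unique(memb)), 2)
  expect_equal(memb[["Aa_a|larva"]], memb[["G1"]])
  expect_false(memb[["Aa_a|larva"]] == memb[["G3"]])
  expect_gte(modularityQ(part),
             modularityScore(net, structure(seq_along(memb),
                                            names = names(memb))))
  # bit-reproducible for a fixed seed
  part2 <- louvainPartition(net, seed = 3)
  expect_identical(clusterAssignments(part), clusterAssignments(part2))
})

test_that("louvain beats random partitions on any graph", {
  net <- randomBipartite(5, 5, seed = 8)
  part <- louvainPartition(net, seed = 1, nRestarts = 5)
  nodes <- c(tickNodes(net), hostNodes(net))
  set.seed(99)
  for (i in 1:100) {
    rand <- structure(sample(1:4, length(nodes), replace = TRUE),
                      names = nodes)
    expect_gte(modularityQ(part) + 1e-12, modularityScore(net, rand))
  }
})

test_that("cluster switching is detected from the partition", {
  memb <- c("Aa_pa|larva" = 1L, "Aa_pa|nymph" = 4L, "Aa_pa|adult" = 5L,
            "Ix_bo|larva" = 2L, "Ix_bo|nymph" = 2L, "Ix_bo|adult" = 2L,
            "G1" = 1L)
  part <- new("NetworkPartition", membership = memb, modularity = 0.1,
              resolution = 1, seed = 1L, nRestarts = 1L)
  rep <- detectClusterSwitch(part, names(memb)[1:6])
  ap <- rep$species[rep$species$species == "Aa_pa", ]
  expect_true(ap$switches)
  expect_equal(ap$n_distinct_clusters, 3)
  ib <- rep$species[rep$species$species == "Ix_bo", ]
  expect_false(ib$switches)
  expect_equal(rep$genus$n_switching[rep$genus$genus == "Aa"], 1)
  expect_error(detectClusterSwitch(part, "no_pipe_here"), "malformed|missing")
})

test_that("planted switching species are exactly recovered under clean sampling", {
  # noise-free module draws: between-module affinity 0 and full clade use
  cfg <- syntheticConfig(nModules = 4, hostsPerModule = 8, ticksPerModule = 5,
                         fracSwitching = 0.3, fracCladeRestricted = 1,
                         betweenModuleAffinity = 0, hostsPerStage = 8,
                         recordsPerEdgeMean = 5, overdispersion = 0, seed = 21)
  sim <- simulateRecords(cfg)
  net <- buildNetwork(expandPairs(sim$records))
  part <- louvainPartition(net, seed = 2, nRestarts = 5)
  rep <- detectClusterSwitch(part, tickNodes(net))
  flagged <- sort(rep$species$species[rep$species$switches])
  expect_equal(flagged, sim$truth$switching)
  expect_length(flagged, round(0.3 * 20))
})

test_that("NODF matches its defining cases and is permutation invariant", {
  # strictly nested staircase
  stair <- buildNetwork(data.frame(
    tick_node_id = c(rep("Aa_a|larva", 3), rep("Bb_b|larva", 2), "Cc_c|larva"),
    host_genus = c("G1", "G2", "G3", "G1", "G2", "G1"), weight = 1))
  expect_equal(nestednessIndex(stair), 100)
  # checkerboard: no overlap at all
  checker <- buildNetwork(data.frame(
    tick_node_id = c("Aa_a|larva", "Bb_b|larva"),
    host_genus = c("G1", "G2"), weight = 1))
  expect_equal(nestednessIndex(checker), 0)
  expect_error(nestednessIndex(buildNetwork(toyPairs()[3, ])), "at least 2")
  # random matrices against the direct pairwise formula, and invariance
  for (seed in 1:25) {
    net <- randomBipartite(6, 6, p = 0.5, seed = seed)
    m <- (incidenceMatrix(net) > 0) * 1
    expect_equal(nestednessIndex(net), nodfDirect(m), tolerance = 1e-10)
    perm <- m[sample(nrow(m)), sample(ncol(m))]
    expect_equal(nodfDirect(perm), nodfDirect(m), tolerance = 1e-10)
  }
})

test_that("cluster subnetworks honour the two link configurations", {
  pairs <- data.frame(
    tick_node_id = c("Aa_a|larva", "Aa_a|larva", "Aa_a|adult",
                     "Bb_b|adult", "Bb_b|adult"),
    host_genus = c("G1", "G2", "G3", "G3", "G4"),
    weight = 1)
  net <- buildNetwork(pairs)
  memb <- c("Aa_a|larva" = 1L, "G1" = 1L, "G2" = 1L,
            "Aa_a|adult" = 2L, "Bb_b|adult" = 2L, "G3" = 2L, "G4" = 2L)
  part <- new("NetworkPartition", membership = memb, modularity = 0.2,
              resolution = 1, seed = 1L, nRestarts = 1L)
  intra1 <- extractClusterSubnetwork(net, part, 1, FALSE)
  expect_setequal(edgeTable(intra1)$host, c("G1", "G2"))
  # mode (ii) on cluster 2 pulls in no new edge for a closed cluster
  intra2 <- extractClusterSubnetwork(net, part, 2, FALSE)
  full2 <- extractClusterSubnetwork(net, part, 2, TRUE)
  expect_equal(edgeTable(intra2), edgeTable(full2))
  # mode (ii) on cluster 1 brings the adult's host G3 via... no: it brings
  # edges of cluster-1 members; Aa_a|larva has none outside, so identical
  full1 <- extractClusterSubnetwork(net, part, 1, TRUE)
  expect_equal(edgeTable(full1), edgeTable(intra1))
  expect_error(extractClusterSubnetwork(net, part, 99), "unknown cluster")
  # mode (i) edges are always a subset of mode (ii) edges
  sim <- simulateRecords(syntheticConfig(nModules = 3, hostsPerModule = 6,
                                         ticksPerModule = 4,
                                         hostsPerStage = 4, seed = 2))
  netS <- buildNetwork(expandPairs(sim$records))
  partS <- louvainPartition(netS, seed = 1)
  for (k in unique(clusterAssignments(partS))) {
    ei <- edgeTable(extractClusterSubnetwork(netS, partS, k, FALSE))
    ee <- edgeTable(extractClusterSubnetwork(netS, partS, k, TRUE))
    expect_true(all(paste(ei$tick, ei$host) %in% paste(ee$tick, ee$host)))
  }
})

test_that("external links add the partners of stage-switching members", {
  # tick with adult in cluster 1 and larva in cluster 2: mode (ii) on
  # cluster 1 adds the larva? no -- it adds edges of cluster-1 MEMBERS;
  # the adult node is the member, its own external edge comes in
  pairs <- data.frame(
    tick_node_id = c("Aa_a|adult", "Aa_a|adult", "Bb_b|larva"),
    host_genus = c("G1", "G2", "G2"), weight = 1)
  net <- buildNetwork(pairs)
  memb <- c("Aa_a|adult" = 1L, "G1" = 1L, "Bb_b|larva" = 2L, "G2" = 2L)
  part <- new("NetworkPartition", membership = memb, modularity = 0,
              resolution = 1, seed = 1L, nRestarts = 1L)
  full1 <- extractClusterSubnetwork(net, part, 1, TRUE)
  expect_true("G2" %in% hostNodes(full1))
  expect_equal(nrow(edgeTable(full1)), 2)
  intra1 <- extractClusterSubnetwork(net, part, 1, FALSE)
  expect_equal(nrow(edgeTable(intra1)), 1)
})

test_that("graph exports carry modes, clusters and weights", {
  net <- buildNetwork(toyPairs())
  part <- louvainPartition(net, seed = 1)
  gml <- tempfile(fileext = ".graphml")
  exportGraphML(net, gml, part)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_setequal(igraph::V(g)$mode, c("tick", "host"))
  expect_equal(sort(igraph::E(g)$weight), c(1, 2, 3))
  gexf <- tempfile(fileext = ".gexf")
  exportGEXF(net, gexf, part)
  doc <- readLines(gexf)
  expect_true(any(grepl("defaultedgetype=\"undirected\"", doc)))
  expect_equal(sum(grepl("<edge ", doc)), 3)
})
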