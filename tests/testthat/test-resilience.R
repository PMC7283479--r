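fullSharing <- function() buildNetwork(data.frame(
  tick_node_id = rep(c("Aa_a|adult", "Bb_b|adult"), each = 4),
  host_genus = rep(sprintf("G%d", 1:4), 2), weight = 1))

test_that("shared-partner means match full, disjoint and brute-force cases", {
  expect_equal(meanSharedPartners(fullSharing(), "ticks"), 4)
  disjoint <- buildNetwork(data.frame(
    tick_node_id = c("Aa_a|adult", "Bb_b|adult"),
    host_genus = c("G1", "G2"), weight = 1))
  expect_equal(meanSharedPartners(disjoint, "ticks"), 0)
  single <- buildNetwork(data.frame(tick_node_id = "Aa_a|adult",
                                    host_genus = c("G1", "G2"), weight = 1))
  expect_error(meanSharedPartners(single, "ticks"), "single")
  # brute-force pair intersection oracle
  for (seed in 1:10) {
    net <- randomBipartite(5, 6, seed = seed)
    m <- incidenceMatrix(net) > 0
    for (mode in c("ticks", "hosts")) {
      mm <- if (mode == "ticks") m else t(m)
      tot <- 0; np <- 0
      for (i in 1:(nrow(mm) - 1)) for (j in (i + 1):nrow(mm)) {
        tot <- tot + sum(mm[i, ] & mm[j, ]); np <- np + 1
      }
      expect_equal(meanSharedPartners(net, mode), tot / np)
    }
  }
})

test_that("niche overlap is Morisita-Horn on weighted profiles", {
  identical2 <- buildNetwork(data.frame(
    tick_node_id = rep(c("Aa_a|adult", "Bb_b|adult"), each = 2),
    host_genus = rep(c("G1", "G2"), 2), weight = c(2, 4, 1, 2)))
  expect_equal(nicheOverlap(identical2, "ticks"), 1)  # proportional profiles
  disjoint <- buildNetwork(data.frame(
    tick_node_id = c("Aa_a|adult", "Bb_b|adult"),
    host_genus = c("G1", "G2"), weight = 1))
  expect_equal(nicheOverlap(disjoint, "ticks"), 0)
  # 3-tick toy against the closed formula 2*sum(pq)/(sum(p^2)+sum(q^2))
  w <- rbind(c(3, 1, 0), c(1, 1, 2), c(0, 2, 2))
  net <- buildNetwork(data.frame(
    tick_node_id = rep(sprintf("Aa_t%d|adult", 1:3), each = 3),
    host_genus = rep(sprintf("G%d", 1:3), 3),
    weight = as.vector(t(w)))[as.vector(t(w)) > 0, ])
  mh <- function(p, q) {
    p <- p / sum(p); q <- q / sum(q)
    2 * sum(p * q) / (sum(p^2) + sum(q^2))
  }
  hand <- mean(c(mh(w[1, ], w[2, ]), mh(w[1, ], w[3, ]), mh(w[2, ], w[3, ])))
  expect_equal(nicheOverlap(net, "ticks"), hand, tolerance = 1e-10)
  # binary alternative
  expect_equal(nicheOverlap(disjoint, "ticks", method = "jaccard"), 0)
})

test_that("partner diversity is the weight-weighted mean Shannon index", {
  oneHost <- buildNetwork(data.frame(
    tick_node_id = sprintf("Aa_t%d|adult", 1:3),
    host_genus = sprintf("G%d", 1:3), weight = c(5, 1, 9)))
  expect_equal(partnerDiversity(oneHost, "ticks"), 0)
  uniform <- buildNetwork(data.frame(
    tick_node_id = "Aa_a|adult", host_genus = sprintf("G%d", 1:4),
    weight = 2))
  expect_equal(partnerDiversity(uniform, "ticks"), log(4))
  # two ticks: H1 = ln 2 with total weight 10, H2 = 0 with weight 30
  mixed <- buildNetwork(data.frame(
    tick_node_id = c("Aa_a|adult", "Aa_a|adult", "Bb_b|adult"),
    host_genus = c("G1", "G2", "G1"), weight = c(5, 5, 30)))
  expect_equal(partnerDiversity(mixed, "ticks"), 10 * log(2) / 40)
})

test_that("robustness is the exponential of tick partner diversity", {
  expect_equal(robustnessIndex(0), 1)
  uniform <- buildNetwork(data.frame(
    tick_node_id = "Aa_a|adult", host_genus = sprintf("G%d", 1:6),
    weight = 3))
  expect_equal(robustnessIndex(partnerDiversity(uniform, "ticks")), 6)
  expect_error(robustnessIndex(-1), ">= 0")
})

test_that("extinction cascades follow forced and redundant extremes", {
  oneOnOne <- buildNetwork(data.frame(tick_node_id = "Aa_a|adult",
                                      host_genus = "G1", weight = 1))
  cv <- extinctionCascade(oneOnOne, nReps = 1, seed = 1)
  expect_equal(cv$curve$y_mean, c(1, 0))
  redundant <- fullSharing()   # every tick on all 4 hosts
  cv2 <- extinctionCascade(redundant, nReps = 5, seed = 1)
  expect_equal(cv2$curve$y_mean, c(1, 1, 1, 1, 0))
})

test_that("a fixed-seed random pass replays a manual simulation", {
  net <- randomBipartite(4, 5, seed = 3)
  cv <- extinctionCascade(net, nReps = 1, seed = 42)
  m <- incidenceMatrix(net) > 0
  set.seed(42)
  ord <- sample.int(ncol(m))
  y <- numeric(ncol(m) + 1)
  alive <- rep(TRUE, nrow(m)); removed <- logical(ncol(m))
  y[1] <- 1
  for (i in seq_along(ord)) {
    removed[ord[i]] <- TRUE
    y[i + 1] <- sum(rowSums(m[, !removed, drop = FALSE]) > 0) / nrow(m)
  }
  expect_equal(cv$curve$y_mean, y)
})

test_that("curves are monotone non-increasing under every policy", {
  for (seed in 1:5) {
    net <- randomBipartite(5, 6, seed = seed)
    for (pol in c("random", "most_connected_first", "least_connected_first")) {
      cv <- extinctionCascade(net, policy = pol, nReps = 20, seed = seed)
      expect_true(all(diff(cv$curve$y_mean) <= 1e-12))
      expect_equal(cv$curve$y_mean[1], 1)
      expect_equal(cv$curve$y_mean[length(cv$curve$y_mean)], 0)
    }
  }
  expect_error(extinctionCascade(fullSharing(), policy = "nope"))
})

test_that("hyperbolic slope fits are exact on noiseless curves", {
  x <- seq(0, 1, length.out = 21)
  expect_equal(as.numeric(fitExtinctionSlope(data.frame(x = x, y = 1 - x))),
               1, tolerance = 1e-6)
  expect_equal(as.numeric(fitExtinctionSlope(data.frame(x = x, y = 1 - x^2))),
               2, tolerance = 1e-6)
  expect_error(fitExtinctionSlope(data.frame(x = 0:1, y = c(1, 0))),
               ">= 3")
})

test_that("slope recovery tolerates observation noise", {
  x <- seq(0, 1, length.out = 21)
  set.seed(8)
  errs <- replicate(25, {
    y <- 1 - x^1.5 + rnorm(21, sd = 0.02)
    as.numeric(fitExtinctionSlope(data.frame(x = x, y = y))) - 1.5
  })
  expect_lt(max(abs(errs)), 0.1)
})

test_that("duplicating a host never lowers the deterministic slope", {
  for (seed in 1:5) {
    net <- randomBipartite(5, 5, seed = seed)
    e <- edgeTable(net)
    dup <- e[e$host == hostNodes(net)[1], ]
    dup$host <- "GenusCopy"
    net2 <- buildNetwork(data.frame(tick_node_id = c(e$tick, dup$tick),
                                    host_genus = c(e$host, dup$host),
                                    weight = c(e$weight, dup$weight)))
    a1 <- as.numeric(fitExtinctionSlope(
      extinctionCascade(net, "most_connected_first")))
    a2 <- as.numeric(fitExtinctionSlope(
      extinctionCascade(net2, "most_connected_first")))
    expect_gte(a2, a1 - 1e-6)
  }
})

test_that("more replicates move the slope by less than its standard error", {
  net <- randomBipartite(8, 10, p = 0.4, seed = 7)
  fitOne <- function(reps, seed) as.numeric(fitExtinctionSlope(
    extinctionCascade(net, nReps = reps, seed = seed)))
  few <- vapply(1:10, function(s) fitOne(99, s), 1.0)
  many <- fitOne(999, 1)
  expect_lt(abs(many - mean(few)), 3 * sd(few))
})

test_that("configuration comparison is 100 percent for closed clusters", {
  pairs <- do.call(rbind, lapply(1:2, function(k) data.frame(
    tick_node_id = rep(sprintf("Aa_m%dt%d|adult", k, 1:3), each = 2),
    host_genus = sprintf("G%d_%d", k, c(1, 2, 2, 3, 3, 1)), weight = k)))
  net <- buildNetwork(pairs)
  memb <- structure(rep(1:2, each = 6),
                    names = c(outer(c("Aa_m1t1|adult", "Aa_m1t2|adult",
                                      "Aa_m1t3|adult", "G1_1", "G1_2", "G1_3",
                                      "Aa_m2t1|adult", "Aa_m2t2|adult",
                                      "Aa_m2t3|adult", "G2_1", "G2_2", "G2_3"),
                                    "", paste0)))
  part <- new("NetworkPartition", membership = memb, modularity = 0.4,
              resolution = 1, seed = 1L, nRestarts = 1L)
  cmp <- compareConfigurations(net, part, nReps = 30, seed = 2)
  expect_true(all(cmp$percent$percent == 100, na.rm = TRUE))
  expect_true(all(is.na(cmp$percent$reason) | cmp$percent$percent == 100))
})

test_that("external generalist partners raise shared-host means", {
  # cluster 1 = two ticks on G1..G3; an external tick's larva also uses
  # G1..G3 heavily, and cluster-1 hosts gain an external shared tick
  pairs <- data.frame(
    tick_node_id = c(rep("Aa_a|adult", 2), rep("Bb_b|adult", 2),
                     rep("Cc_c|larva", 3), "Cc_c|larva"),
    host_genus = c("G1", "G2", "G2", "G3", "G1", "G2", "G3", "GX"),
    weight = 1)
  net <- buildNetwork(pairs)
  memb <- c("Aa_a|adult" = 1L, "Bb_b|adult" = 1L, "G1" = 1L, "G2" = 1L,
            "G3" = 1L, "Cc_c|larva" = 2L, "GX" = 2L)
  part <- new("NetworkPartition", membership = memb, modularity = 0.1,
              resolution = 1, seed = 1L, nRestarts = 1L)
  intra <- extractClusterSubnetwork(net, part, 1, FALSE)
  full <- extractClusterSubnetwork(net, part, 1, TRUE)
  expect_gt(meanSharedPartners(full, "hosts"),
            meanSharedPartners(intra, "hosts"))
  cmp <- compareConfigurations(net, part, nReps = 20, seed = 1)
  row <- cmp$percent[cmp$percent$cluster == 1 &
                     cmp$percent$index == "mean_shared_ticks_per_host", ]
  expect_gt(row$percent, 100)
})

test_that("robustness identity holds across clusters and configurations", {
  sim <- simulateRecords(syntheticConfig(nModules = 3, hostsPerModule = 8,
                                         ticksPerModule = 5,
                                         hostsPerStage = 4, seed = 31))
  net <- buildNetwork(expandPairs(sim$records))
  part <- louvainPartition(net, seed = 1)
  cmp <- compareConfigurations(net, part, nReps = 20, seed = 3)
  v <- cmp$values
  for (k in unique(v$cluster)) for (cf in unique(v$configuration)) {
    rob <- v$value[v$cluster == k & v$configuration == cf &
                   v$index == "robustness"]
    pdiv <- v$value[v$cluster == k & v$configuration == cf &
                    v$index == "partner_diversity_ticks"]
    if (!is.na(rob)) expect_equal(rob, exp(pdiv), tolerance = 1e-12)
  }
})
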