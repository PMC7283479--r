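# Independent reference implementations used as test oracles. These are
# deliberately naive (enumeration, Floyd-Warshall, direct formulas) and
# share no code with the package internals they check.

# --- fixtures -----------------------------------------------------------

balancedTree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# random weighted bipartite network with nT ticks x nH hosts
randomBipartite <- function(nT, nH, p = 0.6, maxWeight = 5, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nT * nH, 1, p), nT, nH)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  w <- matrix(sample.int(maxWeight, nT * nH, replace = TRUE), nT, nH) * m
  ticks <- sprintf("Tickus_t%02d|%s", seq_len(nT),
                   c("larva", "nymph", "adult")[(seq_len(nT) - 1) %% 3 + 1])
  hosts <- sprintf("Genus%02d", seq_len(nH))
  idx <- which(w > 0, arr.ind = TRUE)
  buildNetwork(data.frame(tick_node_id = ticks[idx[, 1]],
                          host_genus = hosts[idx[, 2]],
                          weight = w[w > 0]))
}

starNetwork <- function(nLeaves = 4) buildNetwork(data.frame(
  tick_node_id = "Aa_hub|adult",
  host_genus = sprintf("G%d", seq_len(nLeaves)), weight = 1))

# symmetric weighted adjacency of a BipartiteNetwork, node order t..., h...
adjacencyOf <- function(net) {
  nodes <- c(tickNodes(net), hostNodes(net))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- edgeTable(net)
  A[cbind(match(e$tick, nodes), match(e$host, nodes))] <- e$weight
  A + t(A)
}

# --- modularity: exhaustive partition enumeration -----------------------

# all set partitions of n elements as restricted-growth codes
setPartitionsOf <- function(n) {
  out <- vector("list", 0)
  rec <- function(code, maxUsed) {
    if (length(code) == n) { out[[length(out) + 1L]] <<- code; return() }
    for (k in seq_len(maxUsed + 1L)) rec(c(code, k), max(maxUsed, k))
  }
  rec(integer(), 0L)
  out
}

# Q from the modularity matrix: (1/2W) sum_ij [A_ij - k_i k_j / 2W] d(ci,cj)
qFromModularityMatrix <- function(A, code) {
  W2 <- sum(A)
  k <- rowSums(A)
  M <- A - outer(k, k) / W2
  sum(M[outer(code, code, "==")]) / W2
}

maxEnumeratedQ <- function(A, partitions = setPartitionsOf(nrow(A))) {
  max(vapply(partitions, function(p) qFromModularityMatrix(A, p), 1.0))
}

# --- betweenness: Floyd-Warshall distances + path-count recursion -------

bruteBetweenness <- function(A) {
  A <- (A > 0) * 1
  n <- nrow(A)
  INF <- n + 1
  D <- ifelse(A > 0, 1, INF); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- D[i, k] + D[k, ]
    upd <- dk < D[i, ]
    D[i, upd] <- dk[upd]
  }
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (t in order(D[s, ])) if (t != s && D[s, t] <= n)
      sigma[s, t] <- sum(sigma[s, A[, t] > 0 & D[s, ] == D[s, t] - 1])
  }
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n))
    if (D[s, t] <= n && sigma[s, t] > 0)
      for (v in seq_len(n)) if (v != s && v != t &&
                                D[s, v] + D[v, t] == D[s, t])
        b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
  b
}

# --- NODF: direct paired-overlap formula --------------------------------

nodfDirect <- function(m) {
  pairedSum <- function(mm) {
    fills <- rowSums(mm)
    n <- nrow(mm); s <- 0; np <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      np <- np + 1
      hi <- if (fills[i] >= fills[j]) i else j
      lo <- if (fills[i] >= fills[j]) j else i
      if (fills[hi] > fills[lo] && fills[lo] > 0)
        s <- s + 100 * sum(mm[hi, ] * mm[lo, ]) / fills[lo]
    }
    c(s, np)
  }
  a <- pairedSum(m); b <- pairedSum(t(m))
  unname((a[1] + b[1]) / (a[2] + b[2]))
}

# --- phylogeny ----------------------------------------------------------

# PD by summing branch lengths on the union of root-to-tip edge paths
pdByNodepath <- function(tree, tips) {
  root <- ape::Ntip(tree) + 1L
  edgeKey <- paste(tree$edge[, 1], tree$edge[, 2])
  used <- character()
  for (tip in match(tips, tree$tip.label)) {
    np <- ape::nodepath(tree, from = root, to = tip)
    used <- union(used, paste(np[-length(np)], np[-1]))
  }
  sum(tree$edge.length[match(used, edgeKey)])
}

# exact SES-MPD null: enumerate every k-subset of tips
exactSubsetMPD <- function(tree, k) {
  dis <- stats::cophenetic(tree)
  tips <- tree$tip.label
  apply(utils::combn(length(tips), k), 2, function(ix) {
    d <- dis[ix, ix]
    mean(d[upper.tri(d)])
  })
}

# --- misc ---------------------------------------------------------------

# adjusted Rand index between two labelings (needs mclust)
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

# planted node labels of a synthetic dataset: hosts -> module,
# tick stage nodes -> planted per-stage module
plantedLabels <- function(sim) {
  tsm <- sim$truth$tickStageModule
  tickLab <- structure(tsm$module,
                       names = paste0(tsm$species, "|", tsm$stage))
  c(tickLab, sim$truth$hostModule)
}
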