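#' Read the host-genus phylogeny from a Newick file
#'
#' Polytomies and zero-length branches are accepted; tip labels must be
#' unique host genera. Host-specificity metrics use patristic distances
#' on this tree, so branch lengths are required.
#'
#' @param path Newick file.
#' @return an `ape` `phylo` tree.
#' @export
readHostTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick in ",
                                            path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in host tree")
  if (is.null(tree$edge.length))
    stop("host tree has no branch lengths")
  tree
}

#' Which dataset host genera are on the tree?
#'
#' Genera absent from the tree are excluded from phylogenetic analyses
#' (the tree available rarely covers every genus in a literature
#' compilation); this reports the split.
#'
#' @param tree host `phylo` tree.
#' @param genera character vector of host genera used in the data.
#' @return list `present`, `missing` (sorted character vectors).
#' @export
hostTreeCoverage <- function(tree, genera) {
  genera <- unique(genera)
  list(present = sort(intersect(genera, tree$tip.label)),
       missing = sort(setdiff(genera, tree$tip.label)))
}

#' Faith's phylogenetic diversity of a host set
#'
#' Total branch length of the minimal subtree connecting the host genera
#' and the root (so a single genus scores its root-to-tip path length).
#' Computed with \code{picante::pd}.
#'
#' @param tree host `phylo` tree.
#' @param hostSet character vector of host genera (coerced to a set).
#' @return PD in tree branch-length units.
#' @export
faithPD <- function(tree, hostSet) {
  hostSet <- unique(as.character(hostSet))
  bad <- setdiff(hostSet, tree$tip.label)
  if (length(bad))
    stop("host genera not on the tree: ", paste(bad, collapse = ", "))
  if (!length(hostSet)) stop("empty host set")
  samp <- matrix(as.integer(tree$tip.label %in% hostSet), nrow = 1,
                 dimnames = list("unit", tree$tip.label))
  picante::pd(samp, tree, include.root = TRUE)$PD
}

#' Mean pairwise patristic distance of a host set
#'
#' Unweighted mean of the patristic (sum-of-branch-length) distances over
#' all unordered pairs of distinct host genera; presence-based, so
#' duplicated genera are collapsed.
#'
#' @param tree host `phylo` tree.
#' @param hostSet character vector of >= 2 host genera.
#' @param dis optional precomputed cophenetic matrix (for batch calls).
#' @return MPD in branch-length units.
#' @export
hostMPD <- function(tree, hostSet, dis = NULL) {
  hostSet <- unique(as.character(hostSet))
  bad <- if (is.null(dis)) setdiff(hostSet, tree$tip.label)
         else setdiff(hostSet, rownames(dis))
  if (length(bad))
    stop("host genera not on the tree: ", paste(bad, collapse = ", "))
  if (length(hostSet) < 2)
    stop("MPD undefined for fewer than 2 host genera")
  if (is.null(dis)) dis <- stats::cophenetic(tree)
  d <- dis[hostSet, hostSet]
  mean(d[upper.tri(d)])
}

# mean pairwise distance for each row of a matrix of tip indices
.nullMPD <- function(dis, idx) {
  k <- ncol(idx)
  tot <- numeric(nrow(idx))
  for (a in seq_len(k - 1))
    for (b in seq.int(a + 1, k))
      tot <- tot + dis[cbind(idx[, a], idx[, b])]
  tot / (k * (k - 1) / 2)
}

#' Standardized effect size of MPD against a randomization null
#'
#' Compares the observed MPD of a tick's host set with MPD under random
#' host use: null draws are uniform random tip subsets of the same
#' richness (equivalent to shuffling tip labels). Z = (obs - null mean) /
#' null sd; the one-tailed p is the rank probability that a null MPD is
#' at most the observed one (small p = hosts phylogenetically clustered).
#' When the null is degenerate (e.g. the host set is the whole tree) Z is
#' 0 if the observed value equals the null, otherwise NA with a
#' diagnostic.
#'
#' @param tree host `phylo` tree.
#' @param hostSet character vector of >= 2 host genera on the tree.
#' @param nNull number of null draws (>= 99).
#' @param nullModel only `"tipshuffle"` (uniform tip subsets) in v1.
#' @param seed integer seed; fixes every null draw.
#' @param alternative `"clustering"` (one-tailed, default) or
#'   `"two.sided"`.
#' @param dis optional precomputed cophenetic matrix.
#' @return one-row data.frame: `SR`, `PD`, `MPD_obs`, `null_mean`,
#'   `null_sd`, `Z`, `p`, `n_null`, `seed`, plus a `diagnostic` column.
#' @export
sesMPD <- function(tree, hostSet, nNull = 999L, nullModel = "tipshuffle",
                   seed = 1L, alternative = c("clustering", "two.sided"),
                   dis = NULL) {
  alternative <- match.arg(alternative)
  nullModel <- match.arg(nullModel)
  if (nNull < 99) stop("nNull must be >= 99")
  hostSet <- unique(as.character(hostSet))
  k <- length(hostSet)
  if (k < 2) stop("SES-MPD undefined for fewer than 2 host genera")
  if (is.null(dis)) dis <- stats::cophenetic(tree)
  obs <- hostMPD(tree, hostSet, dis = dis)
  nTips <- nrow(dis)
  set.seed(as.integer(seed))
  idx <- t(replicate(nNull, sample.int(nTips, k)))
  nulls <- .nullMPD(dis, idx)
  nm <- mean(nulls); ns <- stats::sd(nulls)
  diag <- NA_character_
  if (ns > 0) {
    z <- (obs - nm) / ns
  } else if (isTRUE(all.equal(obs, nm))) {
    z <- 0
    diag <- "degenerate null: all draws equal the observed set"
  } else {
    z <- NA_real_
    diag <- "null sd is zero; Z undefined"
  }
  pLow <- (sum(nulls <= obs) + 1) / (nNull + 1)
  p <- if (alternative == "clustering") pLow
       else min(1, 2 * min(pLow, (sum(nulls >= obs) + 1) / (nNull + 1)))
  data.frame(SR = k, PD = faithPD(tree, hostSet), MPD_obs = obs,
             null_mean = nm, null_sd = ns, Z = z, p = p,
             n_null = as.integer(nNull), seed = as.integer(seed),
             diagnostic = diag, stringsAsFactors = FALSE)
}

#' Batch phylogenetic specificity over network units
#'
#' Derives host sets from the network edges and runs [sesMPD()] per unit:
#' per tick species|stage, per cluster (union of the hosts of the
#' cluster's ticks) or per stage class (pooling every species of that
#' stage). Host genera absent from the tree are dropped from the sets
#' (phylogenetic metrics only) and the count is reported; units left with
#' fewer than 2 genera are skipped and listed.
#'
#' @param x a [BipartiteNetwork-class] or a pairs data.frame from
#'   [expandPairs()].
#' @param tree host `phylo` tree.
#' @param grouping `"unit"` (species|stage), `"cluster"`, or `"stage"`.
#' @param partition [NetworkPartition-class]; required for
#'   `grouping = "cluster"`.
#' @param nNull,seed,alternative passed to [sesMPD()]; unit i uses seed
#'   `seed + i - 1`, so the full table is reproducible.
#' @return data.frame with one row per analyzable unit (`unit_id`, `SR`,
#'   `PD`, `MPD_obs`, `null_mean`, `null_sd`, `Z`, `p`, `n_null`,
#'   `seed`); attributes `skipped` (units with SR < 2) and
#'   `genera_dropped` (genera absent from the tree).
#' @export
batchSpecificity <- function(x, tree, grouping = c("unit", "cluster", "stage"),
                             partition = NULL, nNull = 999L, seed = 1L,
                             alternative = "clustering") {
  grouping <- match.arg(grouping)
  pairs <- if (methods::is(x, "BipartiteNetwork")) {
    e <- edgeTable(x)
    data.frame(tick_node_id = e$tick, host_genus = e$host,
               stringsAsFactors = FALSE)
  } else x
  if (!nrow(pairs)) stop("empty grouping: no pairs to analyse")
  info <- splitTickNodeId(pairs$tick_node_id)
  unitOf <- switch(grouping,
    unit = pairs$tick_node_id,
    stage = info$stage,
    cluster = {
      if (is.null(partition))
        stop("grouping = 'cluster' needs a partition")
      cl <- clusterAssignments(partition)
      missing <- setdiff(pairs$tick_node_id, names(cl))
      if (length(missing))
        stop("tick nodes missing from partition: ",
             paste(missing, collapse = ", "))
      paste0("cluster_", unname(cl[pairs$tick_node_id]))
    })
  hostSets <- lapply(split(pairs$host_genus, unitOf), unique)
  cov <- hostTreeCoverage(tree, unlist(hostSets, use.names = FALSE))
  dropped <- cov$missing
  hostSets <- lapply(hostSets, intersect, y = tree$tip.label)
  skipped <- names(hostSets)[lengths(hostSets) < 2]
  hostSets <- hostSets[lengths(hostSets) >= 2]
  if (!length(hostSets)) stop("no unit has >= 2 host genera on the tree")
  dis <- stats::cophenetic(tree)
  rows <- lapply(seq_along(hostSets), function(i)
    cbind(unit_id = names(hostSets)[i],
          sesMPD(tree, hostSets[[i]], nNull = nNull,
                 seed = as.integer(seed) + i - 1L,
                 alternative = alternative, dis = dis),
          stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "genera_dropped") <- dropped
  out
}
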