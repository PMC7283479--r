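focalMatrix <- function(net, mode = c("ticks", "hosts")) {
  mode <- match.arg(mode)
  m <- incidenceMatrix(net)
  if (mode == "hosts") m <- t(m)
  m
}

#' Mean number of shared partners between same-mode nodes
#'
#' Mean over all unordered pairs of ticks (or hosts) of the number of
#' partners they have in common -- e.g. how many host genera two tick
#' species/stages both exploit. Presence-based.
#'
#' @param net a [BipartiteNetwork-class].
#' @param mode `"ticks"` (shared hosts per tick pair) or `"hosts"`
#'   (shared ticks per host pair).
#' @return mean shared-partner count.
#' @export
meanSharedPartners <- function(net, mode = c("ticks", "hosts")) {
  m <- (focalMatrix(net, mode) > 0) * 1
  n <- nrow(m)
  if (n < 2) stop("mean shared partners undefined for a single ", mode,
                  " node")
  shared <- tcrossprod(m)
  mean(shared[upper.tri(shared)])
}

#' Niche overlap of the interaction profiles
#'
#' Mean pairwise similarity of the weighted interaction profiles of
#' same-mode nodes. Default is Morisita-Horn similarity
#' C = 2 sum(p q) / (sum(p^2) + sum(q^2)) on frequency-normalized
#' profiles (1 = identical host use, 0 = disjoint); a binary Jaccard
#' alternative is available. Nodes with zero total weight are excluded
#' with a warning.
#'
#' @inheritParams meanSharedPartners
#' @param method `"horn"` (Morisita-Horn, weighted) or `"jaccard"`
#'   (binary).
#' @return mean pairwise similarity in \[0, 1\].
#' @export
nicheOverlap <- function(net, mode = c("ticks", "hosts"),
                         method = c("horn", "jaccard")) {
  method <- match.arg(method)
  m <- focalMatrix(net, mode)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-weight node(s) excluded from niche overlap")
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("niche overlap undefined for fewer than 2 nodes")
  d <- if (method == "horn") vegan::vegdist(m, method = "horn")
       else vegan::vegdist((m > 0) * 1, method = "jaccard", binary = TRUE)
  mean(1 - d)
}

#' Weighted mean Shannon partner diversity
#'
#' For each node of the focal mode, the Shannon diversity
#' H = -sum p_j ln p_j of its normalized edge weights; returns the mean
#' of H over nodes, weighted by each node's total interaction weight.
#' Nodes with a single partner contribute H = 0.
#'
#' @inheritParams meanSharedPartners
#' @return weighted mean Shannon diversity (>= 0, nats).
#' @export
partnerDiversity <- function(net, mode = c("ticks", "hosts")) {
  m <- focalMatrix(net, mode)
  w <- rowSums(m)
  keep <- w > 0
  if (!any(keep)) return(0)
  H <- vegan::diversity(m[keep, , drop = FALSE])
  stats::weighted.mean(H, w[keep])
}

#' Robustness index: effective partner number
#'
#' exp of the tick-level weighted mean Shannon partner diversity -- the
#' Hill-number (effective number of equally used partners) version of
#' diversity. A network of ticks each using k hosts equally scores k.
#'
#' @param diversity tick partner diversity from [partnerDiversity()].
#' @return robustness >= 1.
#' @export
robustnessIndex <- function(diversity) {
  if (any(diversity < 0, na.rm = TRUE)) stop("diversity must be >= 0")
  exp(diversity)
}

#' Simulate host-removal extinction cascades
#'
#' Hosts are removed one at a time under the given policy; a tick node
#' goes secondarily extinct when its last remaining host is removed. The
#' curve records the fraction of tick nodes surviving against the
#' fraction of hosts removed, averaged over replicates for the random
#' policy (the degree-ordered policies are single deterministic passes;
#' ties broken by node id).
#'
#' @param net a [BipartiteNetwork-class].
#' @param policy `"random"`, `"most_connected_first"` or
#'   `"least_connected_first"` (host degree at the start of the cascade).
#' @param nReps replicates for the random policy.
#' @param seed integer seed.
#' @return object of class `ExtinctionCurve`: list with `curve`
#'   (data.frame `x`, `y_mean`, `y_sd`), `policy`, `n_reps`, `seed`.
#' @export
extinctionCascade <- function(net, policy = c("random",
                                              "most_connected_first",
                                              "least_connected_first"),
                              nReps = 200L, seed = 1L) {
  policy <- match.arg(policy)
  m <- incidenceMatrix(net) > 0
  nT <- nrow(m); nH <- ncol(m)
  if (nT < 1 || nH < 1) stop("cascade needs at least one tick and one host")
  deg <- colSums(m)
  onePass <- function(order) {
    surv <- numeric(nH + 1)
    remaining <- rowSums(m)
    alive <- nT                       # ticks with no hosts at all never count
    surv[1] <- sum(remaining > 0)
    for (i in seq_len(nH)) {
      h <- order[i]
      hit <- m[, h]
      remaining <- remaining - hit
      surv[i + 1] <- sum(remaining > 0)
    }
    surv / max(1, surv[1])
  }
  if (policy == "random") {
    set.seed(as.integer(seed))
    ys <- vapply(seq_len(max(1L, nReps)),
                 function(r) onePass(sample.int(nH)), numeric(nH + 1))
    curve <- data.frame(x = seq(0, nH) / nH,
                        y_mean = rowMeans(ys),
                        y_sd = apply(ys, 1, stats::sd))
    reps <- as.integer(max(1L, nReps))
  } else {
    ord <- if (policy == "most_connected_first")
      order(-deg, colnames(m)) else order(deg, colnames(m))
    y <- onePass(ord)
    curve <- data.frame(x = seq(0, nH) / nH, y_mean = y, y_sd = 0)
    reps <- 1L
  }
  structure(list(curve = curve, policy = policy, n_reps = reps,
                 seed = as.integer(seed)),
            class = "ExtinctionCurve")
}

#' @export
print.ExtinctionCurve <- function(x, ...) {
  cat("ExtinctionCurve (", x$policy, ", ", x$n_reps, " reps): ",
      nrow(x$curve), " points, final survival ",
      format(x$curve$y_mean[nrow(x$curve)], digits = 3), "\n", sep = "")
  invisible(x)
}

#' Fit the hyperbolic extinction slope
#'
#' Nonlinear least-squares fit of the one-parameter hyperbolic survival
#' model y = 1 - x^a to an extinction curve (x = fraction of hosts
#' removed, y = fraction of ticks surviving). Larger a means survival is
#' held up longer: a more resilient cluster.
#'
#' @param curve an `ExtinctionCurve` or a data.frame with columns `x` and
#'   `y` (or `y_mean`).
#' @return the exponent a (> 0), with the `nls` fit attached as attribute
#'   `fit`.
#' @export
fitExtinctionSlope <- function(curve) {
  df <- if (inherits(curve, "ExtinctionCurve")) curve$curve else curve
  y <- if ("y" %in% names(df)) df$y else df$y_mean
  df <- data.frame(x = df$x, y = y)
  if (nrow(df) < 3) stop("extinction slope needs >= 3 curve points")
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - x^a, data = df, start = list(a = 1),
                      lower = 1e-8, control = minpack.lm::nls.lm.control(
                        maxiter = 200)),
    error = function(e) {
      err <- simpleError(paste0("extinction-slope fit did not converge: ",
                                conditionMessage(e)))
      err$residuals <- df
      stop(err)
    })
  a <- unname(stats::coef(fit)["a"])
  attr(a, "fit") <- fit
  a
}

RESILIENCE_INDICES <- c("mean_shared_hosts_per_tick",
                        "mean_shared_ticks_per_host",
                        "niche_overlap_ticks", "niche_overlap_hosts",
                        "partner_diversity_ticks", "partner_diversity_hosts",
                        "robustness", "extinction_slope")

#' All resilience indices for one (sub)network
#'
#' Computes the partner-sharing, niche-overlap, partner-diversity,
#' robustness and extinction-slope indices for a cluster subnetwork.
#' Indices undefined on the subnetwork (e.g. shared partners with a
#' single tick) are reported as `NA`.
#'
#' @param net a [BipartiteNetwork-class].
#' @param policy,nReps,seed passed to [extinctionCascade()].
#' @return one-row data.frame with the `RESILIENCE_INDICES` columns plus
#'   `n_reps` and `seed`.
#' @export
clusterIndexSet <- function(net, policy = "random", nReps = 200L, seed = 1L) {
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NA_real_)
  pdivT <- safe(partnerDiversity(net, "ticks"))
  slope <- safe(fitExtinctionSlope(
    extinctionCascade(net, policy = policy, nReps = nReps, seed = seed)))
  data.frame(
    mean_shared_hosts_per_tick = safe(meanSharedPartners(net, "ticks")),
    mean_shared_ticks_per_host = safe(meanSharedPartners(net, "hosts")),
    niche_overlap_ticks = safe(nicheOverlap(net, "ticks")),
    niche_overlap_hosts = safe(nicheOverlap(net, "hosts")),
    partner_diversity_ticks = pdivT,
    partner_diversity_hosts = safe(partnerDiversity(net, "hosts")),
    robustness = if (is.na(pdivT)) NA_real_ else robustnessIndex(pdivT),
    extinction_slope = as.numeric(slope),
    n_reps = as.integer(nReps), seed = as.integer(seed))
}

#' Compare cluster indices between link configurations
#'
#' Every resilience index is computed per cluster under the intra-only
#' configuration (mode i: the cluster in isolation) and the with-external
#' configuration (mode ii: the cluster plus all links of its members to
#' other clusters), and expressed as a percentage of the intra-only
#' value: 100 means no change, below 100 a decrease when external links
#' are considered.
#'
#' @param net the full [BipartiteNetwork-class].
#' @param partition a [NetworkPartition-class].
#' @param policy,nReps,seed passed to [extinctionCascade()].
#' @return list with `values` (long data.frame: cluster, configuration,
#'   index, value) and `percent` (cluster, index, percent; `NA` with the
#'   reason when undefined).
#' @export
compareConfigurations <- function(net, partition, policy = "random",
                                  nReps = 200L, seed = 1L) {
  clusters <- sort(unique(clusterAssignments(partition)))
  vals <- list(); pcts <- list()
  for (k in clusters) {
    intra <- extractClusterSubnetwork(net, partition, k, FALSE)
    full <- extractClusterSubnetwork(net, partition, k, TRUE)
    # same per-cluster seed for both configurations: a closed cluster
    # (identical subnetworks) then yields exactly 100% for every index
    vi <- clusterIndexSet(intra, policy, nReps, seed + k)
    ve <- clusterIndexSet(full, policy, nReps, seed + k)
    for (idx in RESILIENCE_INDICES) {
      vals[[length(vals) + 1L]] <- data.frame(
        cluster = k,
        configuration = c("intra_only", "with_external"),
        index = idx, value = c(vi[[idx]], ve[[idx]]),
        stringsAsFactors = FALSE)
      pct <- if (is.na(vi[[idx]]) || is.na(ve[[idx]]) || vi[[idx]] == 0)
        NA_real_ else 100 * ve[[idx]] / vi[[idx]]
      reason <- if (is.na(pct)) {
        if (is.na(vi[[idx]]) || is.na(ve[[idx]]))
          "index undefined in one configuration" else "intra-only value is zero"
      } else NA_character_
      pcts[[length(pcts) + 1L]] <- data.frame(
        cluster = k, index = idx, percent = pct, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  list(values = do.call(rbind, vals), percent = do.call(rbind, pcts),
       n_reps = as.integer(nReps), seed = as.integer(seed))
}
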