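#' 32-bit FNV-1a hash of a string (config fingerprinting)
#' @keywords internal
#' @noRd
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split to stay
    # inside double precision
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Derive a stage seed from the master seed
#'
#' Counter-based derivation: each pipeline stage owns a fixed counter, so
#' adding a stage never perturbs the random streams of earlier stages.
#' Result is always a valid 32-bit R integer.
#'
#' @param master master seed (integer).
#' @param counter non-negative integer stage counter.
#' @return integer seed.
#' @export
deriveStageSeed <- function(master, counter) {
  as.integer((abs(as.numeric(master)) %% 100000) * 7919 +
             as.numeric(counter) * 104729) %% 2147483647L
}

STAGE_COUNTERS <- c(simulate = 0L, louvain = 1L, phylo = 2L, resilience = 3L)

#' Full-analysis run configuration
#'
#' Either file inputs (`recordsPath`, optional `treePath`) or a
#' [syntheticConfig()] must be given. All stage seeds derive
#' deterministically from `seed` via [deriveStageSeed()].
#'
#' @param recordsPath records CSV (records schema), or `NULL`.
#' @param treePath host Newick, or `NULL` (phylo stage skipped unless a
#'   synthetic config provides the tree).
#' @param synthetic a [syntheticConfig()], or `NULL`.
#' @param minRecords low-record filter threshold, see [filterMinRecords()].
#' @param excludedGenera host genera to exclude, see [excludeHostTaxa()].
#' @param resolution,nRestarts Louvain settings.
#' @param nNull SES-MPD null draws.
#' @param nReps,removalPolicy extinction-cascade settings.
#' @param runPhylo,runResilience stage switches.
#' @param seed master seed.
#' @param outputDir where result files are written.
#' @return object of class `RunConfig`.
#' @export
runConfig <- function(recordsPath = NULL, treePath = NULL, synthetic = NULL,
                      minRecords = 3L, excludedGenera = character(),
                      resolution = 1, nRestarts = 20L, nNull = 999L,
                      nReps = 200L, removalPolicy = "random",
                      runPhylo = TRUE, runResilience = TRUE, seed = 1L,
                      outputDir = tempfile("ticknet_run_")) {
  if (is.null(recordsPath) && is.null(synthetic))
    stop("provide recordsPath or a synthetic config")
  if (!is.null(synthetic) && !inherits(synthetic, "SyntheticConfig"))
    stop("synthetic must be a syntheticConfig()")
  structure(list(recordsPath = recordsPath, treePath = treePath,
                 synthetic = synthetic, minRecords = as.integer(minRecords),
                 excludedGenera = excludedGenera,
                 resolution = resolution, nRestarts = as.integer(nRestarts),
                 nNull = as.integer(nNull), nReps = as.integer(nReps),
                 removalPolicy = removalPolicy, runPhylo = runPhylo,
                 runResilience = runResilience, seed = as.integer(seed),
                 outputDir = outputDir),
            class = "RunConfig")
}

configHash <- function(config) {
  cfg <- unclass(config)
  cfg$outputDir <- NULL
  if (!is.null(cfg$synthetic)) cfg$synthetic <- unclass(cfg$synthetic)
  fnv1a32(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                        null = "null")))
}

writeStamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the complete analysis pipeline
#'
#' Orchestrates records -> network -> clustering/centrality -> phylogeny
#' -> resilience, writes every result table (CSV with a config-hash
#' header comment), the GraphML/GEXF exports, a JSON echo of the
#' configuration, and a run log. Deterministic for a fixed configuration:
#' re-running yields byte-identical result files.
#'
#' @param config a [runConfig()].
#' @return invisible result bundle (class `TickNetRun`): all intermediate
#'   objects plus `files`, `log` and `configHash`.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("ticknet ", as.character(utils::packageVersion("ticknet")),
       " | config ", hash, " | master seed ", config$seed)

  # --- inputs ------------------------------------------------------------
  truth <- NULL; tree <- NULL
  if (!is.null(config$synthetic)) {
    sim <- simulateRecords(config$synthetic)
    records <- sim$records; tree <- sim$tree; truth <- sim$truth
    note("simulate: ", nrow(records), " records, ",
         length(unique(records$tick_species)), " species, ",
         length(attr(tree, "moduleMap")), " host genera")
  } else {
    records <- readRecords(config$recordsPath)
    note("read: ", nrow(records), " records from ", config$recordsPath)
  }
  if (!is.null(config$treePath)) tree <- readHostTree(config$treePath)
  if (config$runPhylo && is.null(tree))
    stop("stage 'phylo' requested but no host tree available ",
         "(set treePath or runPhylo = FALSE)")

  # --- records_io --------------------------------------------------------
  ex <- excludeHostTaxa(records, config$excludedGenera)
  fl <- filterMinRecords(ex$records, config$minRecords)
  records <- fl$records
  note("filter: ", ex$report$n_records_in, " -> ", ex$report$n_records_out,
       " after host exclusion; -> ", fl$report$n_records_out,
       " after min-records (threshold ", config$minRecords, ")")
  pairs <- expandPairs(records)
  note("pairs: ", nrow(pairs), " tick/stage-host pairs, total weight ",
       sum(pairs$weight))

  # --- network_core ------------------------------------------------------
  net <- buildNetwork(pairs)
  part <- louvainPartition(net, resolution = config$resolution,
                           seed = deriveStageSeed(config$seed,
                                                  STAGE_COUNTERS["louvain"]),
                           nRestarts = config$nRestarts)
  switch <- detectClusterSwitch(part, tickNodes(net))
  nodf <- tryCatch(nestednessIndex(net), error = function(e) NA_real_)
  note("network: ", length(tickNodes(net)), " tick nodes, ",
       length(hostNodes(net)), " hosts, ", nrow(edgeTable(net)),
       " edges; ", length(unique(clusterAssignments(part))),
       " clusters, Q = ", format(modularityQ(part), digits = 4),
       "; NODF = ", format(nodf, digits = 4))

  # --- centrality --------------------------------------------------------
  cent <- betweennessTable(net, partition = part)
  meanBnc <- clusterMeanBNC(cent, part)

  # --- phylo_structure ---------------------------------------------------
  spec <- NULL; relation <- NULL
  if (config$runPhylo) {
    spec <- batchSpecificity(net, tree, grouping = "unit",
                             nNull = config$nNull,
                             seed = deriveStageSeed(config$seed,
                                                    STAGE_COUNTERS["phylo"]))
    nsig <- sum(spec$p < 0.05, na.rm = TRUE)
    note("phylo: ", nrow(spec), " units tested (",
         length(attr(spec, "skipped")), " skipped, ",
         length(attr(spec, "genera_dropped")), " genera off-tree); ",
         nsig, " clustered at p < 0.05")
    relation <- tryCatch(bncMpdRelation(cent, spec),
                         error = function(e) NULL)
  } else note("phylo: not run")

  # --- resilience --------------------------------------------------------
  comparison <- NULL
  if (config$runResilience) {
    comparison <- compareConfigurations(net, part,
      policy = config$removalPolicy, nReps = config$nReps,
      seed = deriveStageSeed(config$seed, STAGE_COUNTERS["resilience"]))
    note("resilience: ", length(unique(comparison$values$cluster)),
         " clusters x 2 configurations, policy ", config$removalPolicy,
         ", ", config$nReps, " reps")
  } else note("resilience: not run")

  # --- outputs -----------------------------------------------------------
  od <- config$outputDir
  files <- c(records = file.path(od, "records_filtered.csv"),
             pairs = file.path(od, "pairs.csv"),
             partition = file.path(od, "partition.csv"),
             switches = file.path(od, "switch_report.csv"),
             centrality = file.path(od, "centrality.csv"),
             cluster_bnc = file.path(od, "cluster_mean_bnc.csv"),
             graphml = file.path(od, "network.graphml"),
             gexf = file.path(od, "network.gexf"),
             config = file.path(od, "config.json"),
             log = file.path(od, "run_log.txt"))
  writeStamped(records, files["records"], hash)
  writeStamped(pairs, files["pairs"], hash)
  memb <- clusterAssignments(part)
  writeStamped(data.frame(node_id = names(memb),
                          mode = ifelse(names(memb) %in% hostNodes(net),
                                        "host", "tick"),
                          cluster = unname(memb)),
               files["partition"], hash)
  writeStamped(switch$species, files["switches"], hash)
  writeStamped(cent, files["centrality"], hash)
  writeStamped(meanBnc, files["cluster_bnc"], hash)
  exportGraphML(net, files["graphml"], part)
  exportGEXF(net, files["gexf"], part)
  if (!is.null(spec)) {
    files["specificity"] <- file.path(od, "specificity.csv")
    writeStamped(spec, files["specificity"], hash)
  }
  if (!is.null(comparison)) {
    files["resilience_values"] <- file.path(od, "resilience_values.csv")
    files["resilience_percent"] <- file.path(od, "resilience_percent.csv")
    writeStamped(comparison$values, files["resilience_values"], hash)
    writeStamped(comparison$percent, files["resilience_percent"], hash)
  }
  cfgOut <- unclass(config)
  cfgOut$synthetic <- if (!is.null(cfgOut$synthetic))
    unclass(cfgOut$synthetic)
  jsonlite::write_json(c(cfgOut, list(config_hash = hash)), files["config"],
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log, files["log"])

  invisible(structure(list(
    config = config, configHash = hash, records = records, pairs = pairs,
    net = net, partition = part, switch = switch, nestedness = nodf,
    centrality = cent, clusterBNC = meanBnc, specificity = spec,
    bncMpd = relation, comparison = comparison, truth = truth, tree = tree,
    filterReports = list(exclusion = ex$report, minRecords = fl$report),
    files = files, log = log), class = "TickNetRun"))
}

#' @export
print.TickNetRun <- function(x, ...) {
  cat("TickNetRun (config ", x$configHash, ") -- ",
      length(unique(clusterAssignments(x$partition))), " clusters, Q = ",
      format(modularityQ(x$partition), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Human-readable summary of a full run
#'
#' Cluster sizes, switching species with their stage-to-cluster maps,
#' nestedness, per-cluster mean centrality, significant phylogenetic
#' clustering counts, and the resilience percent-change table; stages
#' that were not run are marked as such.
#'
#' @param bundle a `TickNetRun` from [runFullAnalysis()].
#' @return the summary text, invisibly; printed to the console.
#' @export
summarizeRun <- function(bundle) {
  stopifnot(inherits(bundle, "TickNetRun"))
  memb <- clusterAssignments(bundle$partition)
  out <- c(
    sprintf("== ticknet run %s ==", bundle$configHash),
    sprintf("Network: %d tick species/stage nodes, %d host genera, %d edges",
            length(tickNodes(bundle$net)), length(hostNodes(bundle$net)),
            nrow(edgeTable(bundle$net))),
    sprintf("Clusters: %d (Q = %.4f); sizes: %s",
            length(unique(memb)), modularityQ(bundle$partition),
            paste(as.integer(table(memb)), collapse = ", ")),
    sprintf("Nestedness (NODF): %s",
            if (is.na(bundle$nestedness)) "not computed"
            else sprintf("%.1f", bundle$nestedness)))
  sw <- bundle$switch$species
  swY <- sw[sw$switches, , drop = FALSE]
  out <- c(out, sprintf("Cluster-switching species: %d of %d",
                        nrow(swY), nrow(sw)))
  if (nrow(swY))
    out <- c(out, paste0("  ", swY$species, "  [", swY$stage_map, "]"))
  mb <- bundle$clusterBNC
  out <- c(out, "Mean tick betweenness per cluster:",
           sprintf("  cluster %d: %s", mb$cluster,
                   ifelse(is.na(mb$mean_bnc), "no ticks",
                          sprintf("%.1f", mb$mean_bnc))))
  if (!is.null(bundle$specificity)) {
    sp <- bundle$specificity
    out <- c(out, sprintf(
      "Phylogenetic clustering: %d of %d species/stage units at p < 0.05 (%.0f%%)",
      sum(sp$p < 0.05, na.rm = TRUE), nrow(sp),
      100 * mean(sp$p < 0.05, na.rm = TRUE)))
    if (!is.null(bundle$bncMpd) && !is.na(bundle$bncMpd$rho))
      out <- c(out, sprintf("  BNC vs MPD-Z Spearman rho = %.2f (n = %d)",
                            bundle$bncMpd$rho, bundle$bncMpd$n))
  } else out <- c(out, "Phylogenetic clustering: not run")
  if (!is.null(bundle$comparison)) {
    pc <- bundle$comparison$percent
    out <- c(out, "Resilience percent change (with external links / intra-only x 100):")
    for (k in sort(unique(pc$cluster))) {
      d <- pc[pc$cluster == k, ]
      out <- c(out, sprintf("  cluster %d: %s", k,
        paste(sprintf("%s=%s", sub("_per_.*", "", d$index),
                      ifelse(is.na(d$percent), "NA",
                             sprintf("%.0f", d$percent))),
              collapse = " ")))
    }
  } else out <- c(out, "Resilience: not run")
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
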