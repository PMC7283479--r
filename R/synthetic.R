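#' Configuration for the synthetic tick-host data generator
#'
#' Validated parameter list describing the simulated community: a host
#' phylogeny whose basal clades are the planted modules, tick species
#' with per-stage host ranges drawn from those modules, and overdispersed
#' record counts per realized interaction. Defaults describe the standard
#' simulated community used throughout the package: 4 modules of 16 host
#' genera and 10 tick species each, 30% of species switching module
#' between immature and adult stages, 60% of species strictly
#' clade-restricted, strong within-module affinity (1 vs 0.02), 8 host
#' genera per stage, and negative-binomial record counts (mean 3,
#' overdispersion 0.5).
#'
#' @param nModules number of planted modules (>= 1).
#' @param hostsPerModule host genera per module clade.
#' @param ticksPerModule tick species per module.
#' @param fracSwitching fraction of species whose adults use a different
#'   module than their immatures.
#' @param fracCladeRestricted fraction of species restricted to their
#'   home module clade.
#' @param fracGeneralist fraction of species drawing hosts uniformly
#'   across all clades (disjoint from the clade-restricted set).
#' @param withinModuleAffinity,betweenModuleAffinity module weights for
#'   the host draws of ordinary (neither restricted nor generalist)
#'   species; within must exceed between >= 0.
#' @param hostsPerStage distinct host genera drawn per tick stage.
#' @param recordsPerEdgeMean mean record count per realized interaction.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @param treeModel only `"yule"` (pure birth, unit rate) in v1.
#' @param seed integer master seed.
#' @return object of class `SyntheticConfig` (a validated list).
#' @export
syntheticConfig <- function(nModules = 4L, hostsPerModule = 16L,
                            ticksPerModule = 10L, fracSwitching = 0.3,
                            fracCladeRestricted = 0.6, fracGeneralist = 0,
                            withinModuleAffinity = 1,
                            betweenModuleAffinity = 0.02,
                            hostsPerStage = 8L, recordsPerEdgeMean = 3,
                            overdispersion = 0.5, treeModel = "yule",
                            seed = 1L) {
  stopifnot(nModules >= 1, hostsPerModule >= 1, ticksPerModule >= 1,
            hostsPerStage >= 1, recordsPerEdgeMean > 0, overdispersion >= 0,
            treeModel == "yule")
  for (f in c(fracSwitching, fracCladeRestricted, fracGeneralist))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (fracCladeRestricted + fracGeneralist > 1)
    stop("fracCladeRestricted + fracGeneralist must be <= 1")
  if (withinModuleAffinity <= betweenModuleAffinity ||
      betweenModuleAffinity < 0)
    stop("need withinModuleAffinity > betweenModuleAffinity >= 0")
  if (hostsPerStage > hostsPerModule)
    stop("infeasible config: hostsPerStage (", hostsPerStage,
         ") exceeds the module clade size (", hostsPerModule, ")")
  if (nModules >= 2 && fracSwitching > 0 && nModules < 2)
    stop("switching needs >= 2 modules")
  structure(list(nModules = as.integer(nModules),
                 hostsPerModule = as.integer(hostsPerModule),
                 ticksPerModule = as.integer(ticksPerModule),
                 fracSwitching = fracSwitching,
                 fracCladeRestricted = fracCladeRestricted,
                 fracGeneralist = fracGeneralist,
                 withinModuleAffinity = withinModuleAffinity,
                 betweenModuleAffinity = betweenModuleAffinity,
                 hostsPerStage = as.integer(hostsPerStage),
                 recordsPerEdgeMean = recordsPerEdgeMean,
                 overdispersion = overdispersion,
                 treeModel = treeModel, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Draw per-edge record counts
#'
#' Negative-binomial counts with the given mean and overdispersion theta
#' (variance = mu + theta mu^2); theta = 0 recovers the Poisson.
#'
#' @param n number of draws.
#' @param mu mean count.
#' @param theta overdispersion (>= 0).
#' @return integer vector (zeros possible; a zero means the sampled
#'   interaction produced no literature record).
#' @export
drawRecordCounts <- function(n, mu, theta) {
  if (theta <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / theta)
}

#' Simulate a host-genus phylogeny
#'
#' Pure-birth (Yule, unit rate) tree with tips relabelled
#' `Host_0001...`. With `nModules > 1` the tree is assembled from
#' `nModules` independent Yule crowns of equal size joined on a pectinate
#' backbone (unit-length backbone branches), so the first `nModules`
#' basal splits delimit the module clades exactly; the host-to-module
#' map is attached as attribute `moduleMap`.
#'
#' @param nTips total number of tips (>= 4; divisible by `nModules`).
#' @param model only `"yule"`.
#' @param seed integer seed (same seed, same Newick string).
#' @param nModules number of module clades (1 = plain Yule tree).
#' @return an `ape` `phylo`; attribute `moduleMap` is a named integer
#'   vector tip -> module.
#' @export
simulateHostTree <- function(nTips, model = "yule", seed = 1L,
                             nModules = 1L) {
  stopifnot(model == "yule")
  if (nTips < 4) stop("need at least 4 tips")
  nModules <- as.integer(nModules)
  if (nTips %% nModules != 0)
    stop("nTips must be divisible by nModules")
  set.seed(as.integer(seed))
  per <- nTips %/% nModules
  if (nModules == 1L) {
    tree <- ape::rphylo(nTips, birth = 1, death = 0)
    tree$tip.label <- sprintf("Host_%04d", seq_len(nTips))
    attr(tree, "moduleMap") <- structure(rep(1L, nTips),
                                         names = tree$tip.label)
    return(tree)
  }
  if (per < 2) stop("each module clade needs >= 2 tips")
  crowns <- character(nModules)
  labels <- vector("list", nModules)
  nxt <- 1L
  for (m in seq_len(nModules)) {
    sub <- ape::rphylo(per, birth = 1, death = 0)
    sub$tip.label <- sprintf("Host_%04d", seq.int(nxt, nxt + per - 1L))
    labels[[m]] <- sub$tip.label
    nxt <- nxt + per
    crowns[m] <- sub("; *$", "", ape::write.tree(sub))
  }
  nwk <- crowns[1]
  for (m in 2:nModules)
    nwk <- paste0("(", nwk, ":1,", crowns[m], ":1)")
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  moduleMap <- structure(rep(seq_len(nModules), times = lengths(labels)),
                         names = unlist(labels))
  attr(tree, "moduleMap") <- moduleMap[tree$tip.label]
  tree
}

#' Simulate an interaction-record table with known ground truth
#'
#' Generates a host tree with planted module clades and a record table in
#' the canonical schema. Every tick species has a home module; each stage
#' draws `hostsPerStage` distinct host genera and a record count per
#' drawn interaction. Species come in three behaviours: clade-restricted
#' (hosts only from the home clade), generalist (uniform across all
#' clades) and ordinary (home module with weight `withinModuleAffinity`,
#' any other with `betweenModuleAffinity`). Switching species give their
#' adult stage a different home module than larva and nymph.
#'
#' @param config a [syntheticConfig()].
#' @return list: `records` (data.frame in the records schema), `tree`
#'   (host phylogeny with `moduleMap`), `truth` (list: `hostModule`,
#'   `tickStageModule`, `cladeRestricted`, `generalist`, `switching`).
#' @export
simulateRecords <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  nTicks <- cfg$nModules * cfg$ticksPerModule
  tree <- simulateHostTree(cfg$nModules * cfg$hostsPerModule,
                           model = cfg$treeModel, seed = cfg$seed,
                           nModules = cfg$nModules)
  hostModule <- attr(tree, "moduleMap")
  hosts <- names(hostModule)
  set.seed(cfg$seed + 1L)

  genera <- c("Amblyomma", "Ixodes", "Haemaphysalis")
  species <- sprintf("%s_sim%03d", genera[(seq_len(nTicks) - 1L) %% 3L + 1L],
                     seq_len(nTicks))
  homeModule <- structure(rep(seq_len(cfg$nModules),
                              each = cfg$ticksPerModule), names = species)

  nRestricted <- round(cfg$fracCladeRestricted * nTicks)
  nGeneralist <- round(cfg$fracGeneralist * nTicks)
  shuffled <- sample(species)
  restricted <- shuffled[seq_len(nRestricted)]
  generalist <- if (nGeneralist > 0)
    shuffled[seq.int(nRestricted + 1L, nRestricted + nGeneralist)]
  else character()
  nSwitch <- round(cfg$fracSwitching * nTicks)
  if (nSwitch > 0 && cfg$nModules < 2)
    stop("infeasible config: switching species need >= 2 modules")
  switching <- sample(species, nSwitch)

  adultModule <- homeModule
  for (s in switching) {
    other <- setdiff(seq_len(cfg$nModules), homeModule[s])
    adultModule[s] <- other[sample.int(length(other), 1L)]
  }

  drawHosts <- function(sp, module) {
    if (sp %in% restricted) {
      pool <- hosts[hostModule == module]
      sample(pool, cfg$hostsPerStage)
    } else if (sp %in% generalist) {
      sample(hosts, cfg$hostsPerStage)
    } else {
      w <- ifelse(hostModule == module, cfg$withinModuleAffinity,
                  cfg$betweenModuleAffinity)
      sample(hosts, cfg$hostsPerStage, prob = w)
    }
  }

  hostClass <- c("Mammalia", "Aves", "Reptilia", "Amphibia")
  rows <- list()
  stageModules <- list()
  for (sp in species) {
    for (stage in RECORD_STAGES) {
      module <- if (stage == "adult") adultModule[[sp]] else homeModule[[sp]]
      stageModules[[length(stageModules) + 1L]] <-
        data.frame(species = sp, stage = stage, module = module,
                   stringsAsFactors = FALSE)
      hs <- drawHosts(sp, module)
      counts <- drawRecordCounts(length(hs), cfg$recordsPerEdgeMean,
                                 cfg$overdispersion)
      if (all(counts == 0)) counts[1] <- 1L   # keep every planted stage observed
      keep <- counts > 0
      if (!any(keep)) next
      hs <- hs[keep]; counts <- counts[keep]
      mh <- hostModule[hs]
      rows[[length(rows) + 1L]] <- data.frame(
        tick_species = sp, stage = stage, host_genus = hs,
        host_family = sprintf("Family_%02d", mh),
        host_order = sprintf("Order_%02d", mh),
        host_class = hostClass[(mh - 1L) %% length(hostClass) + 1L],
        count = as.integer(counts),
        source_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  records$source_id <- sprintf("SIM-%05d", seq_len(nrow(records)))
  rownames(records) <- NULL
  truth <- list(hostModule = hostModule,
                tickStageModule = do.call(rbind, stageModules),
                cladeRestricted = structure(species %in% restricted,
                                            names = species),
                generalist = structure(species %in% generalist,
                                       names = species),
                switching = sort(switching),
                config = cfg)
  list(records = records, tree = tree, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Records CSV (records schema), Newick tree, and the ground truth as
#' JSON, so a generated study can be re-run from files alone.
#'
#' @param sim output of [simulateRecords()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the three paths.
#' @export
writeSyntheticDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pRec <- file.path(dir, "records.csv")
  pTree <- file.path(dir, "host_tree.nwk")
  pTruth <- file.path(dir, "ground_truth.json")
  writeRecords(sim$records, pRec)
  ape::write.tree(sim$tree, pTree)
  truth <- sim$truth
  jsonlite::write_json(list(
    hostModule = as.list(truth$hostModule),
    tickStageModule = truth$tickStageModule,
    cladeRestricted = as.list(truth$cladeRestricted),
    generalist = as.list(truth$generalist),
    switching = truth$switching,
    config = unclass(truth$config)), pTruth, auto_unbox = TRUE,
    pretty = TRUE)
  invisible(c(records = pRec, tree = pTree, truth = pTruth))
}
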