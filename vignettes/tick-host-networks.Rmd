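---
title: "Ticks and hosts as an interacting community: methods behind ticknet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ticks and hosts as an interacting community: methods behind ticknet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Literature records of ticks collected on wild vertebrates are usually read
one association at a time. `ticknet` treats them instead as a community: a
weighted bipartite network whose one mode is tick *species/stage* units
(larva, nymph and adult of the same species are distinct nodes, because
immatures and adults of many species feed on entirely different animals)
and whose other mode is host *genera*. The edge weight is the number of
records of that tick stage on that host genus. From this single object the
package derives four views of the community:

1. **Modularity clusters** — groups of ticks and hosts that interact more
   among themselves than with the rest of the network, and the species
   whose stages sit in *different* clusters (life-stage cluster
   switching).
2. **Centrality** — which ticks bridge otherwise unconnected host groups.
3. **Phylogenetic host specificity** — whether the host genera a tick
   uses are closer on the host phylogeny than random genus sets.
4. **Resilience** — what happens to each cluster when hosts are removed
   and ticks lose their last partners, with and without the links that
   connect clusters to each other.

## Network construction and clustering

Records pass two filters before the network is built. A configurable host
exclusion list removes records on domestic animals (their inclusion
drowns the wild-host signal); the default list is empty and an example
livestock/pet list ships in `inst/extdata/example_config.json`. A
low-record filter drops tick species whose records, summed over stages,
fall below `minRecords`. The threshold genuinely is a free parameter of
this kind of compilation; we default to 3 and always emit a
`FilterReport` so a user can sweep it and see exactly which species enter
the analysis.

Clustering uses weighted Louvain on the two-mode graph treated as
unipartite — deliberately so, since that is how general-purpose graph
tools handle bipartite data, and it keeps ticks and hosts in common
clusters, which is the object of interest. Louvain is greedy and
stochastic; `louvainPartition()` therefore takes a seed (fixed seed =
bit-identical partition), runs `nRestarts` seeded restarts (pipeline
default 20) and keeps the best-Q partition. Cluster ids are relabelled by
descending cluster size so that reports are stable across runs. The Q we
report is always the resolution-1 weighted Newman–Girvan score
`modularityScore()`, whatever resolution produced the assignment.

Nestedness is NODF on the binarized incidence matrix: the mean, over row
pairs and column pairs, of the percentage overlap between the
smaller-fill and larger-fill profile, counting only strictly decreasing
fill. We chose NODF because it is the standard 0–100 index in which
"loosely nested" mutualistic-style matrices score in the 10–30 range;
matrix temperature is out of scope.

## Phylogenetic specificity

For each species/stage (or cluster, or stage class) the host set is read
off the network edges and measured on a host-genus tree:

* **SR** — host genus richness;
* **PD** — Faith's phylogenetic diversity, the branch length of the
  minimal subtree spanning the set *including the root path*, so a
  single-genus set scores its root-to-tip distance (singletons are
  excluded from MPD but still get a PD);
* **MPD** — the unweighted mean patristic distance over unordered genus
  pairs. Presence-based: record counts do not weight the mean, because a
  heavily recorded host would otherwise dominate what is meant to be a
  measure of the *range* of hosts used.

Significance comes from a randomization null: `nNull` (default 999)
uniform random tip subsets of the same richness, equivalent to shuffling
tip labels. `Z = (MPD_obs − mean_null)/sd_null`; the default one-tailed p
is the rank probability (with the +1 small-sample correction) that a null
MPD is at most the observed one, i.e. small p means the hosts are
phylogenetically *clustered*. A two-tailed option exists. Genera missing
from the tree are dropped from the host sets for these metrics only, with
the count reported — genus trees never cover a full literature
compilation. The degenerate case where the host set is the entire tree
yields a zero-variance null equal to the observed value; we report Z = 0
there, and NA with a diagnostic for any other zero-variance null.

## Resilience under two link configurations

Clusters are not closed compartments. Every index is therefore computed
twice per cluster: on the cluster alone (intra-cluster edges only) and on
the cluster's members plus *all* their edges, which pulls in their
partners from other clusters. The comparison is reported as
`100 × with_external / intra_only`, so 100 means no change. Both
configurations use the same cascade seed, which makes the comparison
paired and guarantees exactly 100 for genuinely closed clusters.

The indices: mean shared hosts per tick pair and shared ticks per host
pair (presence-based pair intersections); Morisita–Horn niche overlap of
the weighted interaction profiles (binary Jaccard available by flag);
weighted mean Shannon partner diversity; robustness, defined as
exp(partner diversity) — the effective-partner-number Hill version of
diversity, so it is an identity of the diversity value by construction;
and the extinction slope. For the slope, hosts are removed one at a time
— by default in random order averaged over `nReps = 200` replicates,
with deterministic most/least-connected-first orders available for
sensitivity — a tick node dying when its last host goes, and the
one-parameter hyperbolic survival model `y = 1 − x^a` is fitted to the
mean curve by Levenberg–Marquardt least squares (started at a = 1, which
also converges on exact zero-residual curves). Larger `a` holds survival
up longer: higher resilience. The removal policy and replicate count
behind published versions of such curves are rarely stated; random
removal with a few hundred replicates is the common practice we adopt as
default.

## The synthetic community

Every claim above is testable without any deposited data because the
generator plants known structure:

* **Host tree** — pure-birth (Yule, unit rate) clades of
  `hostsPerModule` genera stitched on a pectinate backbone, so the first
  `nModules` basal splits *are* the module clades. Network modules and
  phylogenetic clades coincide by construction, letting one generator
  serve both the community-detection and the specificity tests.
* **Ticks** — each species has a home module. Three behaviours:
  clade-restricted species draw hosts only from the home clade;
  generalists draw uniformly across all genera; ordinary species draw
  each host from the home module with weight `withinModuleAffinity` (1)
  and any other module with `betweenModuleAffinity` (0.02).
* **Stage switching** — a planted fraction of species
  (`fracSwitching = 0.3`) give their adults a different home module than
  their immatures, emulating the immatures-on-small-hosts /
  adults-on-large-hosts pattern.
* **Record counts** — negative binomial per realized interaction
  (mean 3, overdispersion 0.5), because literature record counts are
  overdispersed; overdispersion 0 recovers the Poisson exactly. A
  sampled interaction with a zero count simply produces no record, as in
  real surveys; if all of a stage's draws are zero one record is kept so
  every planted stage is observable.

Defaults (4 modules × 16 genera × 10 species, 8 genera per stage, 60%
clade-restricted) describe a community of 40 species, 120 species/stage
units and 64 host genera — about a third the size of a full continental
compilation, big enough to exhibit every phenomenon and small enough
that the complete pipeline runs in seconds. What the generator does *not*
emulate: host abundance and geography, record-effort bias correlated
with host popularity, taxonomic synonymy noise, and within-study
correlation of records. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under a clean modular world, not
that any particular empirical dataset will show the same effect sizes.

## Numerical and design choices

* Betweenness is raw (unnormalized) Brandes on unweighted geodesics by
  default — weights measure recording intensity, not distance; a
  `weighted` flag uses 1/weight as distance. Display scaling is
  `log(BNC + 1) × 10` with the natural log.
* Louvain tie-breaking is delegated to the seeded igraph implementation;
  determinism is guaranteed per seed, and restarts explore the
  tie-break space.
* The SES-MPD Monte-Carlo p uses `(r + 1)/(n + 1)`, never exactly zero.
* Slope fits bound `a > 0` and attach the full `nls` object for
  diagnostics; non-convergence is an error carrying the curve.
* Stage seeds derive from the master seed by a fixed counter scheme
  (`deriveStageSeed`), so adding a pipeline stage never shifts the
  random streams of earlier stages; every output CSV carries an FNV-1a
  hash of the configuration in a header comment.
* Problem sizes in the shipped tests and acceptance script: partition
  enumeration on graphs of 4–8 nodes, brute-force betweenness up to 12
  nodes, 1,000 random 6×6 NODF matrices, 100 generator replicates for
  the specificity power/size experiment, 50 seeds for planted-module
  recovery — all chosen as the smallest sizes at which the checked
  property is non-trivial.

## Limitations

Louvain maximizes unipartite modularity; bipartite-specific modularity
(Barber) and Infomap are deliberately out of scope in v1, as are
alternative centralities, MNTD, and live phylogeny retrieval — the tree
is consumed as a Newick file. Reproducing the headline numbers of any
specific published compilation additionally requires that compilation's
record table and its (usually unstated) low-record threshold; the
`FilterReport` is designed to make that sweep easy.
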