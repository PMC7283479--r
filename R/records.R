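#' @importFrom utils read.csv write.csv
#' @importFrom stats aggregate
NULL

RECORD_STAGES <- c("larva", "nymph", "adult")
MANDATORY_COLUMNS <- c("tick_species", "stage", "host_genus")
OPTIONAL_COLUMNS <- c("host_family", "host_order", "host_class",
                      "count", "source_id")

#' Default stage-token normalization table
#'
#' Maps the stage spellings commonly found in literature compilations to
#' the canonical `larva` / `nymph` / `adult` values. The table is a named
#' character vector (token -> canonical stage); matching is
#' case-insensitive. Extend or replace it through the `stageTokens`
#' argument of [readRecords()] when a source uses a different dialect.
#'
#' @return named character vector
#' @export
defaultStageTokens <- function() {
  c(l = "larva", larva = "larva", larvae = "larva",
    n = "nymph", nymph = "nymph", nymphs = "nymph",
    a = "adult", adult = "adult", adults = "adult",
    m = "adult", f = "adult", male = "adult", female = "adult")
}

normalizeStage <- function(tokens, stageTokens = defaultStageTokens()) {
  unname(stageTokens[tolower(trimws(as.character(tokens)))])
}

#' Read tick-host interaction records from CSV
#'
#' Parses a table of literature records (one row = one record of a tick
#' species at a given life stage on a host genus) into the canonical
#' record schema. Column names are mapped through `columnMap`, stage
#' tokens are normalized through `stageTokens`, and every row either
#' becomes a valid record or is reported as malformed with its line
#' number.
#'
#' @param path CSV file path.
#' @param columnMap named character vector mapping schema fields
#'   (`tick_species`, `stage`, `host_genus`, optionally `host_family`,
#'   `host_order`, `host_class`, `count`, `source_id`) to column names in
#'   the file. Defaults to identity naming.
#' @param stageTokens stage normalization table, see [defaultStageTokens()].
#' @param sep field delimiter.
#' @param strict if `TRUE` (default) malformed rows raise an error naming
#'   their line numbers; if `FALSE` they are dropped with a warning.
#' @return data.frame of validated records with columns `tick_species`,
#'   `stage`, `host_genus`, `host_family`, `host_order`, `host_class`,
#'   `count`, `source_id`.
#' @export
readRecords <- function(path, columnMap = NULL,
                        stageTokens = defaultStageTokens(),
                        sep = ",", strict = TRUE) {
  if (!file.exists(path)) stop("record file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "#",
                  fileEncoding = "UTF-8")
  if (is.null(columnMap)) columnMap <- character()
  fields <- c(MANDATORY_COLUMNS, OPTIONAL_COLUMNS)
  colFor <- function(field) if (field %in% names(columnMap))
    columnMap[[field]] else field
  for (field in MANDATORY_COLUMNS)
    if (!colFor(field) %in% names(raw))
      stop("mandatory column missing from ", path, ": '", colFor(field),
           "' (schema field '", field, "')")
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
    tick_species = trimws(as.character(raw[[colFor("tick_species")]])),
    stage = as.character(raw[[colFor("stage")]]),
    host_genus = trimws(as.character(raw[[colFor("host_genus")]])))
  for (field in c("host_family", "host_order", "host_class", "source_id"))
    out[[field]] <- if (colFor(field) %in% names(raw))
      as.character(raw[[colFor(field)]]) else NA_character_
  out$count <- if (colFor("count") %in% names(raw))
    suppressWarnings(as.integer(raw[[colFor("count")]])) else 1L
  out$count[is.na(out$count)] <- 1L
  out$stage <- normalizeStage(out$stage, stageTokens)

  # line numbers in the file: +1 for header
  bad <- which(is.na(out$stage) | out$tick_species == "" |
               out$host_genus == "" | out$count < 1)
  if (length(bad)) {
    msg <- paste0("malformed record rows (file line numbers): ",
                  paste(bad + 1L, collapse = ", "),
                  " [unknown stage token, empty species/genus, or count < 1]")
    if (strict) stop(msg) else {
      warning(msg, "; rows dropped")
      out <- out[-bad, , drop = FALSE]
    }
  }
  out <- out[, c(MANDATORY_COLUMNS, OPTIONAL_COLUMNS)]
  rownames(out) <- NULL
  out
}

#' Write records back to CSV (round-trip safe)
#'
#' @param records record data.frame as returned by [readRecords()].
#' @param path output CSV path.
#' @export
writeRecords <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

newFilterReport <- function(nIn, nOut, droppedTicks = character(),
                            droppedHosts = character(), threshold = NA_integer_) {
  structure(list(n_records_in = nIn, n_records_out = nOut,
                 dropped_tick_species = sort(unique(droppedTicks)),
                 dropped_host_genera = sort(unique(droppedHosts)),
                 threshold_used = threshold,
                 empty_output = nOut == 0L && nIn > 0L),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport:", x$n_records_in, "->", x$n_records_out, "records")
  if (!is.na(x$threshold_used)) cat(" (threshold ", x$threshold_used, ")", sep = "")
  cat("\n")
  if (length(x$dropped_tick_species))
    cat("  dropped tick species:", length(x$dropped_tick_species), "\n")
  if (length(x$dropped_host_genera))
    cat("  dropped host genera:", length(x$dropped_host_genera), "\n")
  if (x$empty_output) cat("  WARNING: all records removed\n")
  invisible(x)
}

#' Exclude records on listed host genera
#'
#' Removes records whose host genus is in an exclusion list; the analysis
#' of wild-host communities requires stripping records made on domestic
#' animals, whose inclusion deeply distorts the interaction balance.
#'
#' @param records record data.frame.
#' @param excludedGenera character vector of host genera to drop
#'   (empty = no-op).
#' @return list with elements `records` (survivors) and `report`
#'   (a `FilterReport`).
#' @export
excludeHostTaxa <- function(records, excludedGenera = character()) {
  drop <- records$host_genus %in% excludedGenera
  rep <- newFilterReport(nrow(records), sum(!drop),
                         droppedHosts = records$host_genus[drop])
  if (rep$empty_output) warning("host-taxon exclusion removed every record")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = rep)
}

#' Drop tick species with too few records
#'
#' Tick species reported fewer than `minRecords` times (record counts
#' summed over all stages of the species) are removed entirely. This is
#' the low-record filter applied before network construction: species
#' known from a handful of records carry little information about host
#' range and inflate apparent specificity.
#'
#' @param records record data.frame.
#' @param minRecords integer >= 1; minimum total record count per species.
#' @return list with `records` and `report` as in [excludeHostTaxa()].
#' @export
filterMinRecords <- function(records, minRecords = 3L) {
  if (!is.numeric(minRecords) || length(minRecords) != 1 || minRecords < 1)
    stop("minRecords must be a single integer >= 1")
  tot <- tapply(records$count, records$tick_species, sum)
  keepSpecies <- names(tot)[tot >= minRecords]
  drop <- !(records$tick_species %in% keepSpecies)
  rep <- newFilterReport(nrow(records), sum(!drop),
                         droppedTicks = records$tick_species[drop],
                         threshold = as.integer(minRecords))
  if (rep$empty_output) warning("low-record filter removed every record")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = rep)
}

#' Tick node identifier: "Genus_species|stage"
#' @keywords internal
#' @noRd
tickNodeId <- function(species, stage)
  paste0(gsub(" +", "_", trimws(species)), "|", stage)

splitTickNodeId <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad))
    stop("malformed tick node id (expected 'Genus_species|stage'): ",
         paste(ids[bad], collapse = ", "))
  species <- vapply(parts, `[[`, "", 1L)
  stage <- vapply(parts, `[[`, "", 2L)
  if (!all(stage %in% RECORD_STAGES))
    stop("unknown stage in tick node id: ",
         paste(unique(stage[!stage %in% RECORD_STAGES]), collapse = ", "))
  data.frame(node = ids, species = species, stage = stage,
             genus = sub("_.*", "", species), stringsAsFactors = FALSE)
}

#' Aggregate records into tick/stage-host pairs
#'
#' Collapses validated records to one row per distinct
#' (`Genus_species|stage`, host genus) combination; the pair weight is the
#' summed record count, so total weight is conserved. These pairs are the
#' edges of the bipartite network.
#'
#' @param records record data.frame.
#' @return data.frame with columns `tick_node_id`, `host_genus`, `weight`.
#' @export
expandPairs <- function(records) {
  if (!nrow(records)) return(data.frame(tick_node_id = character(),
                                        host_genus = character(),
                                        weight = integer()))
  df <- data.frame(tick_node_id = tickNodeId(records$tick_species,
                                             records$stage),
                   host_genus = records$host_genus,
                   weight = records$count, stringsAsFactors = FALSE)
  agg <- aggregate(weight ~ tick_node_id + host_genus, data = df, FUN = sum)
  agg <- agg[order(agg$tick_node_id, agg$host_genus), ]
  rownames(agg) <- NULL
  agg
}

#' Serialise a FilterReport to JSON
#' @param report a `FilterReport`.
#' @param path output path.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
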