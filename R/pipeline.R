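#' Run the full census pipeline on a cohort
#'
#' Orchestrates the per-species stages end to end: classify every
#' proteome against a shared, incrementally growing reference
#' database; build the family/subfamily census and summary
#' statistics; build and cluster the presence/absence profile; and,
#' for species with gene/BGC annotations, call P450 membership in BGC
#' regions and tally cluster types. All tabular outputs are written as
#' TSV under `outDir`; every output is a pure function of (inputs,
#' thresholds, parameters), so repeated runs are byte-identical.
#'
#' @param manifest data.frame (or TSV path) with columns `species`,
#'   `proteome` (FASTA path) and optional `genes`, `bgc` (TSV paths;
#'   `NA` or `""` when absent).
#' @param db a [ReferenceDB-class] of named P450s.
#' @param outDir output directory (created if needed), or `NULL` to
#'   skip writing.
#' @param thresholds a [ClassifierThresholds-class].
#' @param params an [AlignmentParams-class] (global mode).
#' @param linkage linkage for [clusterMatrix()].
#' @return list with `results` (all classification rows), `census`
#'   (a [CensusTable-class]), `presence` (a clustered
#'   [PresenceMatrix-class] or `NULL` if no P450s), `memberships`
#'   (BGC membership records), `typeTally` (cluster-type counts),
#'   `bgc` (the [bgcSummary()] list or `NULL`) and `db` (the augmented
#'   database).
#' @export
runCohort <- function(manifest, db, outDir = NULL,
                      thresholds = classifierThresholds(),
                      params = alignmentParams("global"),
                      linkage = "average") {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("species", "proteome") %in% names(manifest)))
    stop("manifest needs columns 'species' and 'proteome'")
  if (anyDuplicated(manifest$species))
    stop("duplicate species in manifest")
  validObject(thresholds); validObject(params)

  allRows <- list()
  for (i in seq_len(nrow(manifest))) {
    run <- classifyProteome(manifest$proteome[i], manifest$species[i],
                            db, thresholds, params)
    allRows[[i]] <- run$results
    db <- run$db
  }
  results <- if (length(allRows)) do.call(rbind, allRows)
             else .emptyClassificationRow()
  census <- buildCensus(results, data.frame(species = manifest$species))

  presence <- NULL
  counted <- results[!is.na(results$family), , drop = FALSE]
  if (nrow(counted) > 0L)
    presence <- clusterMatrix(buildPresenceMatrix(counted),
                              linkage = linkage)

  memberships <- NULL; typeTally <- integer(0); bgc <- NULL
  hasAnno <- all(c("genes", "bgc") %in% names(manifest))
  if (hasAnno) {
    regionList <- list(); geneList <- list()
    for (i in seq_len(nrow(manifest))) {
      g <- manifest$genes[i]; b <- manifest$bgc[i]
      if (is.na(g) || is.na(b) || !nzchar(g) || !nzchar(b)) next
      geneList[[length(geneList) + 1L]] <- readGeneTable(g)
      regionList[[length(regionList) + 1L]] <- parseBgcTable(b)
    }
    if (length(geneList)) {
      memberships <- do.call(rbind, Map(p450sInBgcs, geneList, regionList))
      regions <- suppressWarnings(do.call(c, regionList))
      typeTally <- tallyClusterTypes(regions)
      if (censusTotals(census)$nP450s > 0L)
        bgc <- bgcSummary(memberships, censusTotals(census)$nP450s)
    }
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(as.data.frame(results), file.path(outDir,
                                               "classifications.tsv"))
    exportCensus(census, file.path(outDir, "census_families.tsv"))
    tot <- censusTotals(census)
    writeTsv(data.frame(statistic = names(tot),
                        value = unlist(tot, use.names = FALSE)),
             file.path(outDir, "census_summary.tsv"))
    if (!is.null(presence)) {
      exportPresenceMatrix(presence, file.path(outDir,
                                               "presence_matrix.tsv"))
      if (!is.null(presence@rowDend))
        dendrogramNewick(presence, "row",
                         file.path(outDir, "species_dendrogram.nwk"))
      if (!is.null(presence@colDend))
        dendrogramNewick(presence, "column",
                         file.path(outDir, "family_dendrogram.nwk"))
    }
    if (!is.null(memberships))
      exportBgcMemberships(memberships,
                           file.path(outDir, "bgc_memberships.tsv"))
    if (length(typeTally))
      writeTsv(data.frame(cluster_type = names(typeTally),
                          count = as.integer(typeTally)),
               file.path(outDir, "cluster_type_tally.tsv"))
  }

  list(results = results, census = census, presence = presence,
       memberships = memberships, typeTally = typeTally, bgc = bgc,
       db = db)
}
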