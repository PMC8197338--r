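#' Aggregate classifications into a family/subfamily census
#'
#' Counts named P450s per family and per (family, subfamily), with the
#' percentage contribution of each family to the total. `short` and
#' `rejected` queries are excluded from all totals. The subfamily
#' total does not count the unassigned marker `"_"`.
#'
#' @param results classification rows from [classifyProteome()] (a
#'   [S4Vectors::DataFrame] or data.frame with `species`, `family`,
#'   `subfamily`, `status`).
#' @param roster data.frame of the analyzed cohort with column
#'   `species` (and optionally `genus`; otherwise the genus is the
#'   first whitespace token of the species name). Every species in
#'   `results` must appear.
#' @return a [CensusTable-class].
#' @examples
#' res <- S4Vectors::DataFrame(
#'   species = "Sp one", family = c("202", "202", "153"),
#'   subfamily = "A", status = "existing_subfamily")
#' familyCounts(buildCensus(res, data.frame(species = "Sp one")))
#' @export
buildCensus <- function(results, roster) {
  results <- as.data.frame(results)
  if (!"species" %in% names(roster))
    stop("roster needs a 'species' column")
  if (!"genus" %in% names(roster))
    roster$genus <- sub("\\s.*$", "", roster$species)
  missing <- setdiff(unique(results$species), roster$species)
  missing <- missing[!is.na(missing)]
  if (length(missing))
    stop("species missing from roster: ", paste(missing, collapse = ", "))

  counted <- results[results$status %in%
                       c("existing_subfamily", "new_subfamily",
                         "new_family"), , drop = FALSE]
  n <- nrow(counted)
  if (n > 0L) {
    famTab <- as.data.frame(table(family = counted$family),
                            stringsAsFactors = FALSE)
    names(famTab)[2] <- "count"
    famTab <- famTab[order(famTab$family), , drop = FALSE]
    famTab$percentage <- 100 * famTab$count / n
    subTab <- as.data.frame(
      table(family = counted$family, subfamily = counted$subfamily),
      stringsAsFactors = FALSE)
    names(subTab)[3] <- "count"
    subTab <- subTab[subTab$count > 0L, , drop = FALSE]
    subTab <- subTab[order(subTab$family, subTab$subfamily), , drop = FALSE]
  } else {
    famTab <- data.frame(family = character(), count = integer(),
                         percentage = numeric())
    subTab <- data.frame(family = character(), subfamily = character(),
                         count = integer())
  }
  spWith <- unique(counted$species)
  spWith <- spWith[!is.na(spWith)]
  genWith <- unique(roster$genus[roster$species %in% spWith])
  totals <- list(
    nP450s = n,
    nFamilies = length(unique(famTab$family)),
    nSubfamilies = sum(subTab$subfamily != "_"),
    nShort = sum(results$status == "short"),
    nSpeciesAnalyzed = length(unique(roster$species)),
    nSpeciesWithP450s = length(spWith),
    nGeneraAnalyzed = length(unique(roster$genus)),
    nGeneraWithP450s = length(genWith))
  new("CensusTable",
      familyTable = S4Vectors::DataFrame(famTab, row.names = NULL),
      subfamilyTable = S4Vectors::DataFrame(subTab, row.names = NULL),
      totals = totals)
}

#' @rdname familyCounts
#' @export
setMethod("familyCounts", "CensusTable", function(x) x@familyTable)

#' @rdname subfamilyCounts
#' @export
setMethod("subfamilyCounts", "CensusTable", function(x) x@subfamilyTable)

#' @rdname censusTotals
#' @export
setMethod("censusTotals", "CensusTable", function(x) x@totals)

setMethod("show", "CensusTable", function(object) {
  t <- object@totals
  cat("P450 census:", t$nP450s, "P450s in", t$nFamilies, "families /",
      t$nSubfamilies, "subfamilies\n")
  cat(" species with P450s:", t$nSpeciesWithP450s, "of",
      t$nSpeciesAnalyzed, "| genera:", t$nGeneraWithP450s, "of",
      t$nGeneraAnalyzed, "| short-P450s excluded:", t$nShort, "\n")
})

#' Write a census to a family/subfamily TSV
#'
#' Columns mirror the conventional printed census layout: `family`,
#' `family_count`, `percentage` (two decimals, half-away rounding),
#' `subfamily`, `subfamily_count`; the family columns are repeated on
#' every subfamily row.
#'
#' @param census a [CensusTable-class].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
exportCensus <- function(census, path) {
  ft <- as.data.frame(familyCounts(census))
  st <- as.data.frame(subfamilyCounts(census))
  m <- merge(st, ft, by = "family", sort = TRUE)
  out <- data.frame(family = paste0("CYP", m$family),
                    family_count = m$count.y,
                    percentage = sprintf("%.2f%%",
                                         roundAsPrinted(m$percentage, 2)),
                    subfamily = m$subfamily,
                    subfamily_count = m$count.x)
  writeTsv(out[order(out$family, out$subfamily), ], path)
}

#' Read a printed-style family/subfamily census TSV
#'
#' Parses the census layout in which the family columns are stated on
#' the family's first row and left blank on continuation (subfamily)
#' rows, as printed tables have it; fully repeated family columns are
#' accepted too. The `CYP` prefix and a trailing `%` are stripped.
#'
#' @param path TSV with columns `family`, `family_count`, `percentage`,
#'   `subfamily`, `subfamily_count`.
#' @return a [CensusTable-class] (species/genus totals are `NA`: a
#'   printed census does not carry the roster).
#' @export
readFamilyCensus <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("family", "family_count", "percentage", "subfamily",
            "subfamily_count")
  if (!all(need %in% names(raw)))
    stop("census TSV must have columns: ", paste(need, collapse = ", "))
  # carry family columns forward over blank continuation rows
  fam <- raw$family
  for (i in seq_along(fam))
    if (!nzchar(fam[i])) {
      fam[i] <- fam[i - 1L]
      raw$family_count[i] <- raw$family_count[i - 1L]
    }
  fam <- sub("^CYP", "", fam, ignore.case = TRUE)
  st <- data.frame(family = fam, subfamily = raw$subfamily,
                   count = as.integer(raw$subfamily_count))
  first <- !duplicated(fam)
  ft <- data.frame(family = fam[first],
                   count = as.integer(raw$family_count[first]))
  n <- sum(ft$count)
  ft$percentage <- 100 * ft$count / n
  new("CensusTable",
      familyTable = S4Vectors::DataFrame(ft[order(ft$family), ],
                                         row.names = NULL),
      subfamilyTable = S4Vectors::DataFrame(
        st[order(st$family, st$subfamily), ], row.names = NULL),
      totals = list(nP450s = n, nFamilies = nrow(ft),
                    nSubfamilies = sum(st$subfamily != "_"),
                    nShort = NA_integer_, nSpeciesAnalyzed = NA_integer_,
                    nSpeciesWithP450s = NA_integer_,
                    nGeneraAnalyzed = NA_integer_,
                    nGeneraWithP450s = NA_integer_))
}

#' Average number of P450s per species
#'
#' @param nP450s total number of P450s.
#' @param nSpecies number of species (must be > 0); conventionally the
#'   species that have P450s.
#' @return the quotient (unrounded; see [roundAsPrinted()] for
#'   presentation).
#' @examples
#' averageP450s(874, 241)
#' @export
averageP450s <- function(nP450s, nSpecies) {
  if (any(nSpecies <= 0)) stop("'nSpecies' must be > 0")
  nP450s / nSpecies
}

#' P450 diversity percentage
#'
#' `100 * nFamilies / (nP450s * nSpeciesWithP450s)` — the cross-taxon
#' diversity statistic: family richness normalized by both repertoire
#' size and cohort size. Homogeneous of degree -1 in each denominator
#' term (doubling `nP450s` halves it).
#'
#' @param nFamilies number of P450 families.
#' @param nP450s total number of P450s (> 0).
#' @param nSpeciesWithP450s number of species with P450s (> 0).
#' @return the percentage (unrounded).
#' @examples
#' diversityPercentage(143, 874, 241)  # ~0.0679
#' @export
diversityPercentage <- function(nFamilies, nP450s, nSpeciesWithP450s) {
  if (any(nP450s <= 0) || any(nSpeciesWithP450s <= 0))
    stop("denominators must be > 0")
  100 * nFamilies / (nP450s * nSpeciesWithP450s)
}

#' Percentage of P450s inside BGCs
#'
#' @param nP450sInBgcs number of P450s that are members of BGC regions.
#' @param nP450s total number of P450s (> 0).
#' @return the percentage (unrounded).
#' @examples
#' bgcPercentage(21, 874)  # ~2.40
#' @export
bgcPercentage <- function(nP450sInBgcs, nP450s) {
  if (any(nP450s <= 0)) stop("'nP450s' must be > 0")
  100 * nP450sInBgcs / nP450s
}

#' Compare family sets across taxa
#'
#' Computes, for every non-empty combination of taxa, the families
#' found in exactly those taxa (the Venn regions), plus all pairwise
#' intersection counts and the universal intersection.
#'
#' @param sets named list of character vectors of family tokens.
#' @return list with `regions` (data.frame `taxa`, `count`, `families`;
#'   families sorted and `/`-joined), `pairwise` (symmetric matrix of
#'   intersection sizes), and `universal` (sorted character vector of
#'   families shared by all taxa).
#' @examples
#' compareFamilySets(list(A = c("107", "125"), B = "107",
#'                        C = c("107", "152")))
#' @export
compareFamilySets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be a named list")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  taxa <- names(sets)
  n <- length(taxa)
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L)
    membership <- matrix(membership, nrow = 1L,
                         dimnames = list(NULL, taxa))
  combos <- unlist(lapply(seq_len(n), function(k)
    utils::combn(taxa, k, simplify = FALSE)), recursive = FALSE)
  regions <- do.call(rbind, lapply(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb) &
      rowSums(membership[, setdiff(taxa, cmb), drop = FALSE]) == 0L
    fams <- universe[inside]
    data.frame(taxa = paste(cmb, collapse = "&"),
               count = length(fams),
               families = paste(fams, collapse = "/"))
  }))
  pairwise <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) for (j in seq_len(n))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  universal <- Reduce(intersect, sets)
  list(regions = regions, pairwise = pairwise,
       universal = sort(universal))
}

#' Write the Venn-region family comparison to TSV
#'
#' @param comparison result of [compareFamilySets()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
exportFamilyComparison <- function(comparison, path) {
  writeTsv(comparison$regions, path)
}
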