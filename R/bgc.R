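#' Parse a BGC region table
#'
#' Reads the simplified tab-separated dialect of antiSMASH region
#' exports: columns `species`, `region_id`, `cluster_type`, `contig`,
#' `start`, `end` (1-based, inclusive) and optionally
#' `most_similar_known_cluster` and `similarity` (a percentage; a
#' trailing `%` is stripped). Unknown columns are dropped with a
#' warning. Hybrid regions carry several labels joined by `", "`.
#'
#' @param path TSV path.
#' @return a [GenomicRanges::GRanges], one range per region, with the
#'   above metadata columns.
#' @export
parseBgcTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "region_id", "cluster_type", "contig", "start",
            "end")
  optional <- c("most_similar_known_cluster", "similarity")
  if (!all(need %in% names(df)))
    stop("BGC table must have columns: ", paste(need, collapse = ", "))
  extra <- setdiff(names(df), c(need, optional))
  if (length(extra))
    warning("ignoring unknown BGC table column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  if (any(is.na(start)) || any(is.na(end)))
    stop("malformed region coordinates")
  if (any(start > end))
    stop("region start > end in row(s): ",
         paste(which(start > end), collapse = ", "))
  sim <- if ("similarity" %in% names(df))
    suppressWarnings(as.numeric(sub("%$", "", trimws(df$similarity))))
  else rep(NA_real_, nrow(df))
  if (any(!is.na(sim) & (sim < 0 | sim > 100)))
    stop("similarity must lie in [0, 100]")
  msk <- if ("most_similar_known_cluster" %in% names(df))
    df$most_similar_known_cluster else rep(NA_character_, nrow(df))
  msk[msk %in% c("-", "")] <- NA_character_
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = start, end = end),
    species = df$species, region_id = df$region_id,
    cluster_type = df$cluster_type,
    most_similar_known_cluster = msk, similarity = sim)
}

#' Read a gene coordinate table
#'
#' Columns: `gene_id`, `contig`, `start`, `end` (1-based, inclusive),
#' `strand`, `is_p450` and optionally `cyp_name`.
#'
#' @param path TSV path.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `is_p450`, `cyp_name`.
#' @export
readGeneTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig", "start", "end", "strand", "is_p450")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(df$start > df$end)) stop("gene start > end")
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    gene_id = df$gene_id,
    is_p450 = as.logical(df$is_p450),
    cyp_name = if ("cyp_name" %in% names(df)) df$cyp_name
               else NA_character_)
}

#' Call P450 membership in BGC regions
#'
#' A P450 gene is a member of a region iff its full interval lies
#' within the region on the same contig (full containment, not mere
#' overlap: a gene straddling a region boundary is not a member).
#' Strand is ignored.
#'
#' @param genes a [GenomicRanges::GRanges] from [readGeneTable()] or
#'   [generateGenomeWithBgcs()].
#' @param regions a [GenomicRanges::GRanges] from [parseBgcTable()].
#' @return a [S4Vectors::DataFrame] of membership records: `gene_id`,
#'   `cyp_name`, `species`, `region_id`, `cluster_type`,
#'   `most_similar_known_cluster`, `similarity`.
#' @examples
#' g <- generateGenomeWithBgcs(10, 2, 3, seed = 1)
#' p450sInBgcs(g$genes, g$regions)
#' @export
p450sInBgcs <- function(genes, regions) {
  p450 <- genes[genes$is_p450]
  if (length(p450) == 0L || length(regions) == 0L)
    return(S4Vectors::DataFrame(
      gene_id = character(), cyp_name = character(),
      species = character(), region_id = character(),
      cluster_type = character(),
      most_similar_known_cluster = character(), similarity = numeric()))
  hits <- GenomicRanges::findOverlaps(p450, regions, type = "within",
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  S4Vectors::DataFrame(
    gene_id = p450$gene_id[qi],
    cyp_name = p450$cyp_name[qi],
    species = regions$species[si],
    region_id = regions$region_id[si],
    cluster_type = regions$cluster_type[si],
    most_similar_known_cluster = regions$most_similar_known_cluster[si],
    similarity = regions$similarity[si])
}

#' Tally BGC cluster types
#'
#' Hybrid regions (labels joined by commas) count once per label.
#'
#' @param regions a [GenomicRanges::GRanges] from [parseBgcTable()], or
#'   a character vector of labels.
#' @return named integer vector of counts, decreasing.
#' @examples
#' tallyClusterTypes(c("terpene", "terpene", "NRPS, T1PKS"))
#' @export
tallyClusterTypes <- function(regions) {
  labels <- if (is(regions, "GRanges")) regions$cluster_type else regions
  if (length(labels) == 0L) return(integer(0))
  parts <- unlist(strsplit(labels, ",\\s*"))
  tab <- table(parts)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sort(counts, decreasing = TRUE)
}

#' Summarize P450 membership in BGCs
#'
#' @param memberships membership records from [p450sInBgcs()].
#' @param nP450s total number of counted P450s in the cohort.
#' @return list with `nMembers`, `nSpecies` (contributing species),
#'   `perFamily` (named counts by CYP family of the member P450s) and
#'   `percentage` (identical to [bgcPercentage()]).
#' @examples
#' g <- generateGenomeWithBgcs(10, 2, 3, seed = 1)
#' bgcSummary(p450sInBgcs(g$genes, g$regions), nP450s = 10)
#' @export
bgcSummary <- function(memberships, nP450s) {
  m <- as.data.frame(memberships)
  genes <- unique(m$gene_id)
  fams <- character(0)
  named <- !is.na(m$cyp_name) & !duplicated(m$gene_id)
  if (any(named)) fams <- parseCypName(m$cyp_name[named])$family
  perFamily <- if (length(fams)) {
    tab <- table(fams)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    sort(counts, decreasing = TRUE)
  } else integer(0)
  list(nMembers = length(genes),
       nSpecies = length(unique(m$species[!is.na(m$species)])),
       perFamily = perFamily,
       percentage = bgcPercentage(length(genes), nP450s))
}

#' Write membership records shaped like a published BGC-P450 table
#'
#' @param memberships records from [p450sInBgcs()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
exportBgcMemberships <- function(memberships, path) {
  m <- as.data.frame(memberships)
  writeTsv(m[, c("species", "cyp_name", "cluster_type",
                 "most_similar_known_cluster", "similarity",
                 "gene_id", "region_id")], path)
}
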