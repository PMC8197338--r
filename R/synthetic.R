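#' Draw a random protein sequence
#'
#' Residues are i.i.d. draws from the fixed background frequency table
#' `AA_BACKGROUND` (a Robinson-Robinson-style composition over the 20
#' standard residues). Deterministic per seed.
#'
#' @param length sequence length in residues (> 0).
#' @param seed integer seed.
#' @return amino-acid string.
#' @examples
#' randomProtein(30, seed = 1)
#' @export
randomProtein <- function(length, seed) {
  if (length <= 0) stop("'length' must be a positive number of residues")
  withSeed(seed, paste(sample(names(AA_BACKGROUND), length, replace = TRUE,
                              prob = AA_BACKGROUND), collapse = ""))
}

#' Mutate a sequence to a target identity
#'
#' Substitutes a uniformly chosen set of `round((1 - target) * L)`
#' positions, each with a residue different from the original; no
#' indels are introduced, so the realized ungapped identity equals the
#' target to within `1/L`. This analytic control is what makes
#' threshold-band tests of the classifier possible.
#'
#' @param template amino-acid string.
#' @param target target identity fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return mutated amino-acid string of the same length.
#' @examples
#' mutateToIdentity(randomProtein(100, 1), 0.55, seed = 2)
#' @export
mutateToIdentity <- function(template, target, seed) {
  t0 <- .checkProtein(template, "template")
  if (!is.numeric(target) || target < 0 || target > 1)
    stop("'target' identity must lie in [0, 1]")
  L <- nchar(t0)
  k <- round((1 - target) * L)
  if (k == 0L) return(t0)
  withSeed(seed, {
    s <- strsplit(t0, "", fixed = TRUE)[[1]]
    pos <- sample.int(L, k)
    for (p in pos) {
      alt <- setdiff(AA20, s[p])
      s[p] <- sample(alt, 1L)
    }
    paste(s, collapse = "")
  })
}

#' Synthesize a reference database of named P450s
#'
#' Each name gets an independent random sequence, so distinct families
#' sit near background identity from one another — the regime in which
#' the threshold classifier is exact.
#'
#' @param names character vector of CYP names (e.g. `"CYP202A1"`).
#' @param seed integer seed.
#' @param length sequence length for every entry (default 450, a
#'   typical bacterial P450 size).
#' @return a [ReferenceDB-class].
#' @examples
#' generateReferenceDB(c("CYP202A1", "CYP153A1"), seed = 1)
#' @export
generateReferenceDB <- function(names, seed, length = 450L) {
  parseCypName(names)  # validates
  seqs <- withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, base::length(names))
    vapply(seeds, function(s) randomProtein(length, s), character(1))
  })
  referenceDB(stats::setNames(Biostrings::AAStringSet(seqs), names))
}

#' Generate one synthetic species proteome with known truth
#'
#' Emits one mutated copy of the named reference per identity target,
#' plus truncated fragments (`nShort`, lengths 120-250, below the
#' default short cutoff) and random decoy proteins (`nDecoys`, lengths
#' 350-450). The truth table records the classification verdict each
#' candidate should receive under the default thresholds (40/55,
#' strict): target identity above 0.55 keeps the reference's family
#' and subfamily, above 0.40 keeps the family only, at or below 0.40
#' founds a new family.
#'
#' @param spec a [SyntheticSpeciesSpec-class].
#' @param db a [ReferenceDB-class] containing every `ref` named in the
#'   spec.
#' @return list with `proteome` (named [Biostrings::AAStringSet]) and
#'   `truth` (a [S4Vectors::DataFrame] with `query`, `ref`,
#'   `target_identity`, `expected_status`, `expected_family`,
#'   `expected_subfamily`, `is_short`, `is_decoy`).
#' @examples
#' db <- generateReferenceDB("CYP202A1", seed = 1)
#' generateSpecies(speciesSpec("Brucella abortus",
#'   data.frame(ref = "CYP202A1", identity = 1), seed = 1), db)$truth
#' @export
generateSpecies <- function(spec, db) {
  validObject(spec)
  it <- spec@identityTargets
  nt <- refNames(db)
  missing <- setdiff(it$ref, nt$raw)
  if (length(missing))
    stop("references not in database: ", paste(missing, collapse = ", "))
  tag <- gsub("[^A-Za-z0-9]+", "_", spec@speciesName)
  withSeed(spec@seed, {
    seqs <- character(0); ids <- character(0)
    truth <- list()
    for (i in seq_len(nrow(it))) {
      ref <- it$ref[i]; targ <- it$identity[i]
      template <- as.character(refSequences(db)[[ref]])
      s <- mutateToIdentity(template, targ,
                            sample.int(.Machine$integer.max - 1L, 1L))
      id <- sprintf("%s_p450_%02d", tag, i)
      seqs <- c(seqs, s); ids <- c(ids, id)
      r <- nt[nt$raw == ref, ]
      status <- if (targ > 0.55) "existing_subfamily"
                else if (targ > 0.40) "new_subfamily" else "new_family"
      truth[[length(truth) + 1L]] <- S4Vectors::DataFrame(
        query = id, ref = ref, target_identity = targ,
        expected_status = status,
        expected_family = if (status == "new_family") NA_character_
                          else r$family,
        expected_subfamily = if (status == "existing_subfamily")
                               r$subfamily else NA_character_,
        is_short = FALSE, is_decoy = FALSE)
    }
    for (i in seq_len(spec@nShort)) {
      ref <- if (nrow(nt)) nt$raw[sample.int(nrow(nt), 1L)] else NULL
      len <- sample(120:250, 1L)
      s <- if (is.null(ref))
        randomProtein(len, sample.int(.Machine$integer.max - 1L, 1L))
      else substr(as.character(refSequences(db)[[ref]]), 1L, len)
      id <- sprintf("%s_short_%02d", tag, i)
      seqs <- c(seqs, s); ids <- c(ids, id)
      truth[[length(truth) + 1L]] <- S4Vectors::DataFrame(
        query = id, ref = ref %||% NA_character_, target_identity = NA_real_,
        expected_status = "short", expected_family = NA_character_,
        expected_subfamily = NA_character_, is_short = TRUE,
        is_decoy = FALSE)
    }
    for (i in seq_len(spec@nDecoys)) {
      s <- randomProtein(sample(350:450, 1L),
                         sample.int(.Machine$integer.max - 1L, 1L))
      id <- sprintf("%s_decoy_%02d", tag, i)
      seqs <- c(seqs, s); ids <- c(ids, id)
      truth[[length(truth) + 1L]] <- S4Vectors::DataFrame(
        query = id, ref = NA_character_, target_identity = NA_real_,
        expected_status = "new_family", expected_family = NA_character_,
        expected_subfamily = NA_character_, is_short = FALSE,
        is_decoy = TRUE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      S4Vectors::DataFrame(query = character(), ref = character(),
                           target_identity = numeric(),
                           expected_status = character(),
                           expected_family = character(),
                           expected_subfamily = character(),
                           is_short = logical(), is_decoy = logical())
    list(proteome = stats::setNames(Biostrings::AAStringSet(seqs), ids),
         truth = truth)
  })
}

#' Generate a synthetic genome with BGC regions and known membership
#'
#' Lays `nGenes` non-overlapping genes along one contig, groups
#' `nBgcs` windows of consecutive genes into BGC regions (typed from
#' the standard antiSMASH vocabulary), and marks `nMembers` genes
#' inside those windows as P450s — the planted membership truth. A few
#' P450 genes are also placed outside every region so that the
#' containment stage has true negatives.
#'
#' @param nGenes total genes (>= `nBgcs * 3 + nOutsideP450s`).
#' @param nBgcs number of BGC regions.
#' @param nMembers number of P450 genes planted inside regions.
#' @param nOutsideP450s P450 genes planted outside all regions
#'   (default 2).
#' @param seed integer seed.
#' @param species species label (default `"Synthetic species"`).
#' @param clusterTypes vocabulary to draw region types from.
#' @return list with `genes` (a [GenomicRanges::GRanges] with
#'   `gene_id`, `is_p450`, `cyp_name`), `regions` (a
#'   [GenomicRanges::GRanges] with `species`, `region_id`,
#'   `cluster_type`, `most_similar_known_cluster`, `similarity`) and
#'   `truth` (character vector of member gene ids).
#' @examples
#' g <- generateGenomeWithBgcs(10, 2, 3, seed = 1)
#' g$truth
#' @export
generateGenomeWithBgcs <- function(nGenes = 10L, nBgcs = 2L, nMembers = 3L,
                                   nOutsideP450s = 2L, seed = 1L,
                                   species = "Synthetic species",
                                   clusterTypes = c("terpene", "hserlactone",
                                     "bacteriocin", "betalactone", "NRPS",
                                     "T1PKS", "t2pks", "NAGGN", "ectoine",
                                     "acyl_amino_acids", "NRPS-like")) {
  nGenes <- as.integer(nGenes); nBgcs <- as.integer(nBgcs)
  nMembers <- as.integer(nMembers); nOutsideP450s <- as.integer(nOutsideP450s)
  if (nBgcs > 0L && nGenes < nBgcs * 3L + nOutsideP450s)
    stop("need at least 3 genes per BGC window plus outside P450s")
  withSeed(seed, {
    lens <- sample(900:1500, nGenes, replace = TRUE)
    gaps <- sample(200:2000, nGenes, replace = TRUE)
    starts <- cumsum(c(1L, head(lens + gaps, -1L)))
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    gene_id <- sprintf("gene%03d", seq_len(nGenes))

    # size-safe sample: never the sample(length-1 vector) surprise
    resample <- function(x, n) x[sample.int(length(x), n)]

    # BGC windows: nBgcs disjoint runs of 3 consecutive genes
    windows <- list()
    if (nBgcs > 0L) {
      blockStarts <- sort(resample(seq(1L, nGenes - 2L, by = 3L), nBgcs))
      windows <- lapply(blockStarts, function(b) b:(b + 2L))
    }
    inWindow <- unlist(windows)
    members <- if (nMembers > 0L)
      sort(resample(inWindow, min(nMembers, length(inWindow))))
    else integer(0)
    outside <- setdiff(seq_len(nGenes), inWindow)
    outsideP450 <- if (nOutsideP450s > 0L && length(outside))
      sort(resample(outside, min(nOutsideP450s, length(outside))))
    else integer(0)
    isP450 <- seq_len(nGenes) %in% c(members, outsideP450)
    cyp <- rep(NA_character_, nGenes)
    cyp[isP450] <- sprintf("CYP%dA%d", 5000L + which(isP450), 1L)

    genes <- GenomicRanges::GRanges(
      seqnames = "contig1",
      ranges = IRanges::IRanges(start = starts, end = ends),
      strand = strand,
      gene_id = gene_id, is_p450 = isP450, cyp_name = cyp)

    if (nBgcs > 0L) {
      rstart <- vapply(windows, function(w) max(1L, starts[w[1]] - 100L),
                       integer(1))
      rend <- vapply(windows, function(w) ends[w[length(w)]] + 100L,
                     integer(1))
      regions <- GenomicRanges::GRanges(
        seqnames = "contig1",
        ranges = IRanges::IRanges(start = rstart, end = rend),
        species = species,
        region_id = sprintf("region%02d", seq_len(nBgcs)),
        cluster_type = sample(clusterTypes, nBgcs, replace = TRUE),
        most_similar_known_cluster = NA_character_,
        similarity = NA_real_)
    } else {
      regions <- GenomicRanges::GRanges()
    }
    list(genes = genes, regions = regions,
         truth = gene_id[members])
  })
}

#' Write a gene coordinate table
#'
#' @param genes a [GenomicRanges::GRanges] as produced by
#'   [generateGenomeWithBgcs()].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  writeTsv(data.frame(
    gene_id = genes$gene_id,
    contig = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    is_p450 = genes$is_p450,
    cyp_name = genes$cyp_name), path)
}

#' Write a BGC region table
#'
#' @param regions a [GenomicRanges::GRanges] of BGC regions.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeBgcTable <- function(regions, path) {
  writeTsv(data.frame(
    species = regions$species,
    region_id = regions$region_id,
    cluster_type = regions$cluster_type,
    contig = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    most_similar_known_cluster = regions$most_similar_known_cluster,
    similarity = regions$similarity), path)
}
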