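.classStatuses <- c("existing_subfamily", "new_subfamily", "new_family",
                    "short", "rejected")

.emptyClassificationRow <- function() {
  S4Vectors::DataFrame(
    query = character(), species = character(), length = integer(),
    best_hit = character(), best_identity = numeric(),
    assigned_name = character(), family = character(),
    subfamily = character(), allele = integer(),
    status = character(), provisional = logical())
}

# Decide the status band for a best identity under the threshold rule.
# With strict = TRUE, ">40%" / ">55%" are read literally: exactly 40
# (or 55) falls to the lower band.
.statusForIdentity <- function(identity, thresholds) {
  gt <- if (thresholds@strict) `>` else `>=`
  if (gt(identity, thresholds@subfamilyMin)) "existing_subfamily"
  else if (gt(identity, thresholds@familyMin)) "new_subfamily"
  else "new_family"
}

# Core single-query step: returns the classification row plus the
# (possibly augmented) database.
.classifyOne <- function(sequence, id, species, db, thresholds, params,
                         screen = FALSE, updateDb = TRUE) {
  seqc <- .checkProtein(sequence, paste0("query '", id, "'"))
  len <- nchar(seqc)

  mkrow <- function(best_hit, best_identity, family, subfamily, allele,
                    status, provisional) {
    name <- if (is.na(family)) NA_character_ else
      formatCypName(family, subfamily, allele)
    S4Vectors::DataFrame(
      query = id, species = species, length = len,
      best_hit = best_hit, best_identity = best_identity,
      assigned_name = name, family = family, subfamily = subfamily,
      allele = if (is.na(allele)) NA_integer_ else as.integer(allele),
      status = status, provisional = provisional)
  }

  if (screen && !screenCandidate(seqc))
    return(list(row = mkrow(NA_character_, NA_real_, NA_character_,
                            NA_character_, NA_integer_, "rejected", FALSE),
                db = db))
  if (len < thresholds@shortMinLength)
    return(list(row = mkrow(NA_character_, NA_real_, NA_character_,
                            NA_character_, NA_integer_, "short", FALSE),
                db = db))

  nt <- refNames(db)
  if (length(db) == 0L) {
    fam <- as.character(nextFamilyNumber(db))
    row <- mkrow(NA_character_, NA_real_, fam, "A", 1L, "new_family", TRUE)
  } else {
    ids <- identitiesToSet(seqc, refSequences(db), params)
    best <- which.max(ids)
    bestId <- ids[best]
    status <- .statusForIdentity(bestId, thresholds)
    # flag best-hit conflicts across families
    gt <- if (thresholds@strict) `>` else `>=`
    inFam <- gt(ids, thresholds@familyMin)
    famsHit <- unique(nt$family[inFam])
    if (length(famsHit) > 1L) {
      runner <- setdiff(famsHit, nt$family[best])
      warning("query '", id, "' exceeds the family threshold for ",
              "multiple families (best ", nt$raw[best], "; runner-up ",
              "family ", paste(runner, collapse = ", "),
              "); resolved to the best hit", call. = FALSE)
    }
    row <- switch(status,
      existing_subfamily = {
        fam <- nt$family[best]; sub <- nt$subfamily[best]
        mkrow(nt$raw[best], bestId, fam, sub,
              nextAlleleNumber(db, fam, sub), status, TRUE)
      },
      new_subfamily = {
        fam <- nt$family[best]
        mkrow(nt$raw[best], bestId, fam, nextSubfamilyLetter(db, fam),
              1L, status, TRUE)
      },
      new_family = mkrow(nt$raw[best], bestId,
                         as.character(nextFamilyNumber(db)), "A", 1L,
                         status, TRUE))
  }
  if (updateDb && !is.na(row$assigned_name))
    db <- addReference(db, row$assigned_name, seqc, provisional = TRUE)
  list(row = row, db = db)
}

#' Classify one candidate P450
#'
#' Assigns a candidate to an existing family/subfamily or allocates a
#' new one, following the nomenclature-committee identity rule: global
#' identity to the best-hit named P450 above `subfamilyMin` (55)
#' percent joins its subfamily (next free allele number); above
#' `familyMin` (40) percent joins its family under a newly allocated
#' subfamily letter; otherwise a new (provisional) family number is
#' allocated. Candidates shorter than `shortMinLength` residues are
#' labelled `short` and take no name. Against an empty database every
#' full-length candidate founds a new family.
#'
#' @param sequence amino-acid string (or `AAString`).
#' @param id query identifier.
#' @param db a [ReferenceDB-class].
#' @param thresholds a [ClassifierThresholds-class].
#' @param params an [AlignmentParams-class] (global mode recommended).
#' @param species species label recorded in the result (default `NA`).
#' @return one-row [S4Vectors::DataFrame] with columns `query`,
#'   `species`, `length`, `best_hit`, `best_identity`, `assigned_name`,
#'   `family`, `subfamily`, `allele`, `status`, `provisional`. The
#'   database itself is not modified; use [classifyProteome()] for
#'   incremental runs.
#' @examples
#' db <- generateReferenceDB(c("CYP202A1", "CYP153A1"), seed = 1)
#' q <- as.character(refSequences(db)[["CYP202A1"]])
#' classifyProtein(q, "q1", db)
#' @export
classifyProtein <- function(sequence, id, db,
                            thresholds = classifierThresholds(),
                            params = alignmentParams("global"),
                            species = NA_character_) {
  .classifyOne(sequence, id, species, db, thresholds, params,
               updateDb = FALSE)$row
}

#' Classify a whole proteome incrementally
#'
#' Classifies candidates sequentially in input order. Each named query
#' (including newly allocated families and subfamilies) is added to the
#' database and is available as a hit for later queries in the same
#' run — the incremental greedy clustering used in manual P450 curation.
#'
#' @param proteome an [Biostrings::AAStringSet] with unique names, or a
#'   FASTA path.
#' @param species species label for all queries.
#' @param db a [ReferenceDB-class].
#' @param thresholds a [ClassifierThresholds-class].
#' @param params an [AlignmentParams-class].
#' @param screen apply the heme-motif candidate screen
#'   ([screenCandidate()]) and mark failures `rejected`; default
#'   `FALSE` (the candidate set is trusted).
#' @return a list with `results` (a [S4Vectors::DataFrame], one row per
#'   query) and `db` (the augmented [ReferenceDB-class]).
#' @examples
#' db <- generateReferenceDB("CYP202A1", seed = 1)
#' sp <- generateSpecies(speciesSpec("Brucella abortus",
#'   data.frame(ref = "CYP202A1", identity = 0.9), seed = 2), db)
#' classifyProteome(sp$proteome, "Brucella abortus", db)$results
#' @export
classifyProteome <- function(proteome, species, db,
                             thresholds = classifierThresholds(),
                             params = alignmentParams("global"),
                             screen = FALSE) {
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  ids <- sub("\\s.*$", "", names(proteome) %||%
               paste0("query", seq_along(proteome)))
  if (anyDuplicated(ids))
    stop("duplicate query ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- vector("list", length(proteome))
  for (i in seq_along(proteome)) {
    step <- .classifyOne(as.character(proteome[[i]]), ids[i], species, db,
                         thresholds, params, screen = screen,
                         updateDb = TRUE)
    rows[[i]] <- step$row
    db <- step$db
  }
  results <- if (length(rows)) do.call(rbind, rows)
             else .emptyClassificationRow()
  list(results = results, db = db)
}

#' Heuristic P450 candidate screen
#'
#' Scans for the P450 heme-ligand motif `F-x-x-G-x-x-x-C-x-G`
#' (FxxGxxxCxG), allowing at most one mismatch among the four anchored
#' residues. A crude stand-in for domain-level detection, disabled by
#' default in the pipeline.
#'
#' @param sequence amino-acid string.
#' @param maxMismatch mismatches tolerated among the anchored residues
#'   (default 1).
#' @return `TRUE` when a motif window is found.
#' @examples
#' screenCandidate("AAAFAAGAAACAGAAA")
#' @export
screenCandidate <- function(sequence, maxMismatch = 1L) {
  s <- strsplit(.checkProtein(sequence, "sequence"), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 10L) return(FALSE)
  anchors <- c(1L, 4L, 8L, 10L)
  want <- c("F", "G", "C", "G")
  for (i in seq_len(n - 9L)) {
    mm <- sum(s[i + anchors - 1L] != want)
    if (mm <= maxMismatch) return(TRUE)
  }
  FALSE
}
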