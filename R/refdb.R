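#' Build a reference database from named sequences
#'
#' @param sequences an [Biostrings::AAStringSet] whose names (first
#'   whitespace token) parse as CYP names.
#' @param provisional logical vector flagging classifier-allocated
#'   entries (default all `FALSE`).
#' @return a [ReferenceDB-class].
#' @examples
#' aa <- Biostrings::AAStringSet(c(CYP202A1 = "MKVLLAG", CYP153A1 = "MTTATHW"))
#' referenceDB(aa)
#' @export
referenceDB <- function(sequences = Biostrings::AAStringSet(),
                        provisional = logical(length(sequences))) {
  ids <- sub("\\s.*$", "", names(sequences) %||% character())
  if (length(sequences) && (is.null(names(sequences)) || any(!nzchar(ids))))
    stop("every reference sequence must carry a CYP name")
  names(sequences) <- ids
  nt <- parseCypName(ids)
  nt$provisional <- provisional
  new("ReferenceDB", sequences = sequences, nameTable = nt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a reference database from FASTA
#'
#' Reads a protein FASTA whose record IDs (first token) follow the CYP
#' name grammar and indexes it for classification. Duplicate names and
#' unparsable IDs are errors.
#'
#' @param path FASTA file of named P450s.
#' @return a [ReferenceDB-class].
#' @export
loadReferenceDB <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  referenceDB(aa)
}

#' Write a reference database back to FASTA
#'
#' @param db a [ReferenceDB-class].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writeReferenceDB <- function(db, path) {
  Biostrings::writeXStringSet(refSequences(db), path)
  invisible(path)
}

#' Export sequences for external alignment
#'
#' Writes a multi-FASTA (IDs unchanged) suitable for feeding an
#' external multiple aligner / tree builder; tree building itself is
#' outside this package.
#'
#' @param sequences an [Biostrings::AAStringSet] or [ReferenceDB-class].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
exportAlignmentFasta <- function(sequences, path) {
  if (is(sequences, "ReferenceDB")) sequences <- refSequences(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @describeIn referenceDB sequences accessor
#' @param x a [ReferenceDB-class].
#' @export
setMethod("refSequences", "ReferenceDB", function(x) x@sequences)

#' @describeIn referenceDB parsed-name accessor
#' @export
setMethod("refNames", "ReferenceDB", function(x) x@nameTable)

setMethod("length", "ReferenceDB", function(x) length(x@sequences))

setMethod("show", "ReferenceDB", function(object) {
  nt <- object@nameTable
  cat("ReferenceDB with", length(object), "named P450s in",
      length(unique(nt$family)), "families",
      sprintf("(%d provisional)\n", sum(nt$provisional)))
})

# Next free family number: one above the maximum observed.
nextFamilyNumber <- function(db) {
  fams <- suppressWarnings(as.integer(refNames(db)$family))
  if (!length(fams) || all(is.na(fams))) 1L else max(fams, na.rm = TRUE) + 1L
}

# Next free subfamily letter within a family: A, B, ..., Z, AA, ...
# skipping letters already used (the unassigned marker "_" never
# blocks a letter).
nextSubfamilyLetter <- function(db, family) {
  nt <- refNames(db)
  used <- nt$subfamily[nt$family == family & nt$subfamily != "_"]
  i <- 1L
  repeat {
    cand <- subfamilyLetter(i)
    if (!cand %in% used) return(cand)
    i <- i + 1L
  }
}

# Next allele number within (family, subfamily).
nextAlleleNumber <- function(db, family, subfamily) {
  nt <- refNames(db)
  a <- nt$allele[nt$family == family & nt$subfamily == subfamily]
  if (!length(a)) 1L else max(a) + 1L
}

#' Add one sequence to a reference database
#'
#' Used by the incremental classifier to make newly named P450s
#' available to later queries in the same run.
#'
#' @param db a [ReferenceDB-class].
#' @param name raw CYP name for the new entry.
#' @param sequence amino-acid string.
#' @param provisional flag the entry as classifier-allocated
#'   (default `TRUE`).
#' @return the augmented [ReferenceDB-class].
#' @export
addReference <- function(db, name, sequence, provisional = TRUE) {
  aa <- c(refSequences(db),
          stats::setNames(Biostrings::AAStringSet(sequence), name))
  referenceDB(aa, provisional = c(refNames(db)$provisional, provisional))
}
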