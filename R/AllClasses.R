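#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

setOldClass("hclust")
setClassUnion("hclustOrNULL", c("hclust", "NULL"))

#' AlignmentParams: pairwise alignment parameters
#'
#' Parameters for the affine-gap pairwise alignment engine. The
#' defaults (BLOSUM62, gap open 11, gap extend 1) mirror protein BLAST
#' defaults; classification uses global mode, homolog search local
#' mode. The substitution matrix is restricted to the 20 standard
#' residues plus `X`; `X` is given a uniform floor score so it never
#' counts as identical or similar.
#'
#' @slot mode `"global"` or `"local"`.
#' @slot matrix substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"BLOSUM80"`, `"PAM250"`, ...; anything shipped by Biostrings).
#' @slot gapOpening non-negative gap opening penalty.
#' @slot gapExtension non-negative per-residue gap extension penalty.
#' @export
setClass("AlignmentParams", representation(
  mode = "character",
  matrix = "character",
  gapOpening = "numeric",
  gapExtension = "numeric"
))

setValidity("AlignmentParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("global", "local"))
    msg <- c(msg, "mode must be 'global' or 'local'")
  if (length(object@matrix) != 1L || !nzchar(object@matrix))
    msg <- c(msg, "matrix must be a single matrix name")
  if (object@gapOpening < 0 || object@gapExtension < 0)
    msg <- c(msg, "gap penalties must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct alignment parameters
#'
#' @param mode `"global"` (classification default) or `"local"`
#'   (homolog-search default).
#' @param matrix substitution matrix name; default `"BLOSUM62"`.
#' @param gapOpening gap opening penalty (default 11).
#' @param gapExtension gap extension penalty (default 1).
#' @return an [AlignmentParams-class] object.
#' @examples
#' alignmentParams("global")
#' @export
alignmentParams <- function(mode = c("global", "local"),
                            matrix = "BLOSUM62",
                            gapOpening = 11, gapExtension = 1) {
  mode <- match.arg(mode)
  new("AlignmentParams", mode = mode, matrix = matrix,
      gapOpening = gapOpening, gapExtension = gapExtension)
}

#' PairwiseSummary: summary of one pairwise alignment
#'
#' Holds the aligned pair and the derived statistics consumed by the
#' classifier and homolog stages. `alignmentLength` counts alignment
#' columns after terminal-gap columns are removed (global mode) or
#' within the aligned span (local mode); identity and similarity use it
#' as denominator, matching the usual BLAST reading of "% identity".
#'
#' @slot alignedQuery,alignedSubject aligned rows with `-` gap characters.
#' @slot score optimal alignment score.
#' @slot nIdentical columns with identical non-`X` residues.
#' @slot nSimilar columns whose residue pair scores positively.
#' @slot alignmentLength denominator columns (see above).
#' @slot queryCover,subjectCover fraction of each input's residues
#'   inside the aligned span, in `[0, 1]`.
#' @slot mode `"global"` or `"local"`.
#' @export
setClass("PairwiseSummary", representation(
  alignedQuery = "character",
  alignedSubject = "character",
  score = "numeric",
  nIdentical = "integer",
  nSimilar = "integer",
  alignmentLength = "integer",
  queryCover = "numeric",
  subjectCover = "numeric",
  mode = "character"
))

setValidity("PairwiseSummary", function(object) {
  msg <- character()
  if (object@nIdentical < 0L || object@nIdentical > object@nSimilar ||
      object@nSimilar > object@alignmentLength)
    msg <- c(msg, "need 0 <= nIdentical <= nSimilar <= alignmentLength")
  if (any(c(object@queryCover, object@subjectCover) < 0) ||
      any(c(object@queryCover, object@subjectCover) > 1))
    msg <- c(msg, "covers must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ReferenceDB: database of named P450 reference sequences
#'
#' Couples an amino-acid sequence set with its parsed CYP names and a
#' provisional flag per entry (provisional entries were allocated by
#' the classifier, not assigned by the nomenclature committee). New
#' family numbers are allocated above the maximum observed number; new
#' subfamily letters follow A, B, ..., Z, AA, AB, ... skipping letters
#' already used in that family.
#'
#' @slot sequences an [Biostrings::AAStringSet] named by raw CYP name.
#' @slot nameTable a [S4Vectors::DataFrame] from [parseCypName()], one
#'   row per sequence, plus a logical `provisional` column.
#' @export
setClass("ReferenceDB", representation(
  sequences = "AAStringSet",
  nameTable = "DataFrame"
))

setValidity("ReferenceDB", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (nrow(object@nameTable) != n)
    msg <- c(msg, "nameTable must have one row per sequence")
  if (n > 0L) {
    if (anyDuplicated(object@nameTable$raw))
      msg <- c(msg, paste("duplicate reference names:",
                          paste(unique(object@nameTable$raw[
                            duplicated(object@nameTable$raw)]),
                            collapse = ", ")))
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "reference sequences must be non-empty")
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]",
                 as.character(object@sequences))
    if (any(bad))
      msg <- c(msg, paste("non amino-acid characters in:",
                          paste(object@nameTable$raw[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ClassifierThresholds: identity thresholds for P450 naming
#'
#' The nomenclature rule: a candidate sharing more than `familyMin`
#' percent identity with a named P450 joins its family; more than
#' `subfamilyMin`, its subfamily; otherwise it founds a new family.
#' With `strict = TRUE` (default) the comparisons are strict, so a
#' candidate at exactly 40 or 55 percent falls to the lower band.
#' Candidates shorter than `shortMinLength` residues are flagged
#' `short` and excluded from census totals.
#'
#' @slot familyMin percent identity above which the family is shared
#'   (default 40).
#' @slot subfamilyMin percent identity above which the subfamily is
#'   shared (default 55).
#' @slot shortMinLength minimum full-length candidate size in residues
#'   (default 300).
#' @slot strict strict (`>`) versus inclusive (`>=`) boundary semantics.
#' @export
setClass("ClassifierThresholds", representation(
  familyMin = "numeric",
  subfamilyMin = "numeric",
  shortMinLength = "integer",
  strict = "logical"
))

setValidity("ClassifierThresholds", function(object) {
  msg <- character()
  if (!(object@familyMin > 0 && object@familyMin < object@subfamilyMin &&
        object@subfamilyMin < 100))
    msg <- c(msg, "need 0 < familyMin < subfamilyMin < 100")
  if (object@shortMinLength < 0L)
    msg <- c(msg, "shortMinLength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct classifier thresholds
#'
#' @param familyMin,subfamilyMin percent-identity thresholds
#'   (defaults 40 and 55).
#' @param shortMinLength residues below which a candidate is a
#'   short-P450 (default 300).
#' @param strict strict boundary semantics (default `TRUE`).
#' @return a [ClassifierThresholds-class] object.
#' @examples
#' classifierThresholds()
#' @export
classifierThresholds <- function(familyMin = 40, subfamilyMin = 55,
                                 shortMinLength = 300L, strict = TRUE) {
  new("ClassifierThresholds", familyMin = familyMin,
      subfamilyMin = subfamilyMin,
      shortMinLength = as.integer(shortMinLength), strict = strict)
}

#' HomologThresholds: acceptance thresholds for homolog calls
#'
#' A best homolog is called `present` when percent identity, percent
#' similarity ("homology") and query coverage all clear their minimum;
#' calls within `ambiguousBand` points of any (non-zero) threshold are
#' reported `ambiguous` so borderline evidence stays visible.
#'
#' @slot idMin minimum percent identity (default 25).
#' @slot simMin minimum percent similarity (default 35).
#' @slot covMin minimum percent query coverage (default 50).
#' @slot ambiguousBand width in points of the ambiguity band (default 2).
#' @export
setClass("HomologThresholds", representation(
  idMin = "numeric", simMin = "numeric", covMin = "numeric",
  ambiguousBand = "numeric"
))

setValidity("HomologThresholds", function(object) {
  ok <- all(c(object@idMin, object@simMin, object@covMin) >= 0) &&
    all(c(object@idMin, object@simMin, object@covMin) <= 100) &&
    object@ambiguousBand >= 0
  if (ok) TRUE else "thresholds must lie in [0, 100], band >= 0"
})

#' Construct homolog-call thresholds
#'
#' @param idMin,simMin,covMin minimum percent identity, similarity and
#'   query coverage (defaults 25, 35, 50 — permissive enough for
#'   distantly related genomes).
#' @param ambiguousBand points around each threshold treated as
#'   borderline (default 2).
#' @return a [HomologThresholds-class] object.
#' @examples
#' homologThresholds()
#' @export
homologThresholds <- function(idMin = 25, simMin = 35, covMin = 50,
                              ambiguousBand = 2) {
  new("HomologThresholds", idMin = idMin, simMin = simMin, covMin = covMin,
      ambiguousBand = ambiguousBand)
}

#' CensusTable: family/subfamily census of classified P450s
#'
#' @slot familyTable [S4Vectors::DataFrame] with `family`, `count`,
#'   `percentage` (of all counted P450s).
#' @slot subfamilyTable [S4Vectors::DataFrame] with `family`,
#'   `subfamily`, `count`.
#' @slot totals named list: `nP450s`, `nFamilies`, `nSubfamilies`
#'   (subfamily `"_"`, i.e. unassigned, is not counted), `nShort`,
#'   `nSpeciesAnalyzed`, `nSpeciesWithP450s`, `nGeneraAnalyzed`,
#'   `nGeneraWithP450s`.
#' @export
setClass("CensusTable", representation(
  familyTable = "DataFrame",
  subfamilyTable = "DataFrame",
  totals = "list"
))

setValidity("CensusTable", function(object) {
  msg <- character()
  ft <- object@familyTable
  st <- object@subfamilyTable
  tot <- object@totals
  if (nrow(ft) > 0L && !isTRUE(all.equal(sum(ft$count), tot$nP450s)))
    msg <- c(msg, "family counts must sum to nP450s")
  if (nrow(st) > 0L) {
    sf <- tapply(st$count, st$family, sum)
    fam <- setNames(ft$count, ft$family)
    if (!isTRUE(all.equal(as.numeric(sf[names(fam)]), as.numeric(fam))))
      msg <- c(msg, "subfamily counts must sum to the family count")
  }
  if (length(msg)) msg else TRUE
})

#' PresenceMatrix: species-by-family presence/absence profile
#'
#' Presence is coded `3` and absence `-3`, the coding used by
#' MeV-style heat maps of P450 family profiles. Rows are species that
#' have at least one counted P450; columns are observed families (so no
#' all-absent column can exist). After [clusterMatrix()] the leaf
#' orders and dendrograms of both axes are recorded.
#'
#' @slot mat numeric matrix over \{-3, 3\} with species rownames and
#'   family colnames.
#' @slot rowOrder,colOrder integer leaf orderings.
#' @slot rowDend,colDend `hclust` objects or `NULL` before clustering
#'   (or for single-row/column axes).
#' @export
setClass("PresenceMatrix", representation(
  mat = "matrix",
  rowOrder = "integer",
  colOrder = "integer",
  rowDend = "hclustOrNULL",
  colDend = "hclustOrNULL"
))

setValidity("PresenceMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (length(m) && !all(m %in% c(-3, 3)))
    msg <- c(msg, "matrix values must be -3 or 3")
  if (ncol(m) > 0L && any(colSums(m == 3) == 0L))
    msg <- c(msg, "all-absent family column present")
  if (length(object@rowOrder) != nrow(m) ||
      length(object@colOrder) != ncol(m))
    msg <- c(msg, "orders must index all rows/columns")
  if (length(msg)) msg else TRUE
})

#' PathwayReport: homolog calls for a reference enzyme panel
#'
#' @slot calls [S4Vectors::DataFrame] of homolog calls (all retained
#'   hits, best first, one block per panel enzyme).
#' @slot nEnzymes number of reference enzymes in the panel.
#' @slot nPresent number of enzymes with at least one `present` call.
#' @slot pathwayPresent `TRUE` when every enzyme has a `present` call.
#' @export
setClass("PathwayReport", representation(
  calls = "DataFrame",
  nEnzymes = "integer",
  nPresent = "integer",
  pathwayPresent = "logical"
))

setValidity("PathwayReport", function(object) {
  if (object@nPresent > object@nEnzymes)
    "nPresent cannot exceed nEnzymes" else TRUE
})

#' SyntheticSpeciesSpec: recipe for one synthetic proteome
#'
#' @slot speciesName species label; the first whitespace token is the
#'   genus.
#' @slot identityTargets data.frame with columns `ref` (a reference
#'   name present in the database) and `identity` (target global
#'   identity fraction in `[0, 1]`); one P450 candidate is emitted per
#'   row.
#' @slot nShort number of truncated P450 fragments to emit.
#' @slot nDecoys number of random non-P450 proteins to emit.
#' @slot seed integer fixing all randomness of the species.
#' @export
setClass("SyntheticSpeciesSpec", representation(
  speciesName = "character",
  identityTargets = "data.frame",
  nShort = "integer",
  nDecoys = "integer",
  seed = "integer"
))

setValidity("SyntheticSpeciesSpec", function(object) {
  msg <- character()
  it <- object@identityTargets
  if (nrow(it) && (!all(c("ref", "identity") %in% names(it)) ||
                   any(it$identity < 0 | it$identity > 1)))
    msg <- c(msg, "identityTargets needs columns ref, identity in [0,1]")
  if (object@nShort < 0L || object@nDecoys < 0L)
    msg <- c(msg, "nShort/nDecoys must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic species specification
#'
#' @param speciesName species label (genus = first token).
#' @param identityTargets data.frame(`ref`, `identity`); may have zero
#'   rows for a P450-free species.
#' @param nShort truncated fragments to add (default 0).
#' @param nDecoys random decoy proteins to add (default 0).
#' @param seed integer seed.
#' @return a [SyntheticSpeciesSpec-class] object.
#' @examples
#' speciesSpec("Brucella abortus",
#'             data.frame(ref = "CYP202A1", identity = 1.0), seed = 1)
#' @export
speciesSpec <- function(speciesName,
                        identityTargets = data.frame(ref = character(),
                                                     identity = numeric()),
                        nShort = 0L, nDecoys = 0L, seed = 1L) {
  new("SyntheticSpeciesSpec", speciesName = speciesName,
      identityTargets = identityTargets, nShort = as.integer(nShort),
      nDecoys = as.integer(nDecoys), seed = as.integer(seed))
}
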