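# Substitution matrix cache. Matrices are taken from Biostrings and
# restricted to the 20 standard residues plus X; every score involving
# X is floored at -4 so X never counts as identical or similar.
.matrixCache <- new.env(parent = emptyenv())

cypSubstitutionMatrix <- function(name = "BLOSUM62") {
  key <- name
  if (!is.null(.matrixCache[[key]])) return(.matrixCache[[key]])
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  keep <- c(AA20, "X")
  if (!all(keep %in% rownames(m)))
    stop("matrix ", name, " does not cover the amino-acid alphabet")
  m <- m[keep, keep]
  m["X", ] <- -4
  m[, "X"] <- -4
  .matrixCache[[key]] <- m
  m
}

.checkProtein <- function(x, what) {
  if (!is.character(x)) x <- as.character(x)
  if (length(x) != 1L || !nzchar(x))
    stop(what, " must be a single non-empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x))
    stop(what, " contains characters outside the amino-acid alphabet + X")
  x
}

# Derive identity/similarity/coverage statistics from one aligned pair.
# Terminal-gap columns (present only in global mode) are dropped from
# the denominator so that fragments are judged over their aligned span.
.summarizeAlignedPair <- function(aq, as_, score, mode, qlen, slen,
                                  submat) {
  c1 <- strsplit(aq, "", fixed = TRUE)[[1]]
  c2 <- strsplit(as_, "", fixed = TRUE)[[1]]
  n1 <- which(c1 != "-")
  n2 <- which(c2 != "-")
  if (!length(n1) || !length(n2)) {
    return(new("PairwiseSummary", alignedQuery = "", alignedSubject = "",
               score = score, nIdentical = 0L, nSimilar = 0L,
               alignmentLength = 0L, queryCover = 0, subjectCover = 0,
               mode = mode))
  }
  from <- max(min(n1), min(n2))
  to <- min(max(n1), max(n2))
  keep <- seq(from, to)
  k1 <- c1[keep]
  k2 <- c2[keep]
  resid <- k1 != "-" & k2 != "-"
  ident <- sum(resid & k1 == k2 & k1 != "X")
  simil <- sum(submat[cbind(k1[resid], k2[resid])] > 0)
  new("PairwiseSummary",
      alignedQuery = paste(k1, collapse = ""),
      alignedSubject = paste(k2, collapse = ""),
      score = score,
      nIdentical = as.integer(ident),
      nSimilar = as.integer(simil),
      alignmentLength = length(keep),
      queryCover = sum(k1 != "-") / qlen,
      subjectCover = sum(k2 != "-") / slen,
      mode = mode)
}

#' Align two protein sequences
#'
#' Optimal affine-gap pairwise alignment (Needleman-Wunsch in global
#' mode, Smith-Waterman in local mode) with the statistics the census
#' pipeline consumes: identity, similarity, aligned-span coverage. The
#' dynamic programming itself is delegated to
#' [Biostrings::pairwiseAlignment()]; a gap of length *k* costs
#' `gapOpening + k * gapExtension`.
#'
#' @param query,subject amino-acid strings (or `AAString`s); 20
#'   standard residues plus `X`.
#' @param params an [AlignmentParams-class]; default global/BLOSUM62/11/1.
#' @return a [PairwiseSummary-class].
#' @examples
#' r <- alignPair("HEAGAWGHEE", "PAWHEAE", alignmentParams("local"))
#' percentIdentity(r)
#' @export
alignPair <- function(query, subject, params = alignmentParams("global")) {
  q <- .checkProtein(query, "query")
  s <- .checkProtein(subject, "subject")
  validObject(params)
  m <- cypSubstitutionMatrix(params@matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = q, subject = s, type = params@mode,
    substitutionMatrix = m,
    gapOpening = params@gapOpening, gapExtension = params@gapExtension)
  .summarizeAlignedPair(
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)),
    Biostrings::score(pa), params@mode, nchar(q), nchar(s), m)
}

# Vectorised percent identity of one query against a sequence set;
# used by the classifier (one C-level DP call for the whole set).
identitiesToSet <- function(query, refs, params = alignmentParams("global")) {
  if (!length(refs)) return(numeric())
  q <- .checkProtein(query, "query")
  m <- cypSubstitutionMatrix(params@matrix)
  pa <- Biostrings::pairwiseAlignment(
    pattern = refs, subject = q, type = params@mode,
    substitutionMatrix = m,
    gapOpening = params@gapOpening, gapExtension = params@gapExtension)
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  vapply(seq_along(refs), function(i) {
    r <- .summarizeAlignedPair(ap[i], as_[i], 0, params@mode,
                               Biostrings::width(refs)[i], nchar(q), m)
    percentIdentity(r)
  }, numeric(1))
}

#' @rdname percentIdentity
#' @export
setMethod("percentIdentity", "PairwiseSummary", function(x) {
  if (x@alignmentLength == 0L) return(0)
  100 * x@nIdentical / x@alignmentLength
})

#' @rdname percentSimilarity
#' @export
setMethod("percentSimilarity", "PairwiseSummary", function(x) {
  if (x@alignmentLength == 0L) return(0)
  100 * x@nSimilar / x@alignmentLength
})

#' @rdname alignmentCoverage
#' @export
setMethod("alignmentCoverage", "PairwiseSummary", function(x) {
  c(query = x@queryCover, subject = x@subjectCover)
})

setMethod("show", "PairwiseSummary", function(object) {
  cat(sprintf(
    "PairwiseSummary (%s): score %.1f, identity %.1f%%, similarity %.1f%%\n",
    object@mode, object@score, percentIdentity(object),
    percentSimilarity(object)))
  cat(" ", object@alignedQuery, "\n ", object@alignedSubject, "\n")
})

#' Dump pairwise comparison statistics to TSV
#'
#' @param queries,subjects named character vectors (or `AAStringSet`s)
#'   of equal length; row `i` compares `queries[i]` with `subjects[i]`.
#' @param path output TSV.
#' @param params an [AlignmentParams-class].
#' @return the path, invisibly.
#' @export
writePairwiseTsv <- function(queries, subjects, path,
                             params = alignmentParams("global")) {
  qn <- names(queries) %||% paste0("q", seq_along(queries))
  sn <- names(subjects) %||% paste0("s", seq_along(subjects))
  rows <- lapply(seq_along(queries), function(i) {
    r <- alignPair(as.character(queries[[i]]), as.character(subjects[[i]]),
                   params)
    data.frame(query = qn[i], subject = sn[i],
               identity = percentIdentity(r),
               similarity = percentSimilarity(r),
               query_cover = r@queryCover, subject_cover = r@subjectCover,
               score = r@score)
  })
  writeTsv(do.call(rbind, rows), path)
}
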