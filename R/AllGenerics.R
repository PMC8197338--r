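#' Percent identity of an alignment
#'
#' `100 * nIdentical / alignmentLength`; defined as 0 for a degenerate
#' zero-length aligned span.
#'
#' @param x a [PairwiseSummary-class].
#' @return numeric percentage in `[0, 100]`.
#' @export
setGeneric("percentIdentity", function(x) standardGeneric("percentIdentity"))

#' Percent similarity ("homology") of an alignment
#'
#' `100 * nSimilar / alignmentLength`, counting columns whose residue
#' pair scores positively under the substitution matrix; 0 for a
#' zero-length span.
#'
#' @param x a [PairwiseSummary-class].
#' @return numeric percentage in `[0, 100]`.
#' @export
setGeneric("percentSimilarity",
           function(x) standardGeneric("percentSimilarity"))

#' Query and subject coverage of an alignment
#'
#' @param x a [PairwiseSummary-class].
#' @return named numeric vector `c(query = ..., subject = ...)` of
#'   fractions in `[0, 1]`.
#' @export
setGeneric("alignmentCoverage",
           function(x) standardGeneric("alignmentCoverage"))

#' Reference sequences of a database
#' @param x a [ReferenceDB-class].
#' @return an [Biostrings::AAStringSet].
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' Parsed name table of a reference database
#' @param x a [ReferenceDB-class].
#' @return a [S4Vectors::DataFrame] (one row per entry).
#' @export
setGeneric("refNames", function(x) standardGeneric("refNames"))

#' Per-family census table
#' @param x a [CensusTable-class].
#' @return a [S4Vectors::DataFrame] with `family`, `count`, `percentage`.
#' @export
setGeneric("familyCounts", function(x) standardGeneric("familyCounts"))

#' Per-subfamily census table
#' @param x a [CensusTable-class].
#' @return a [S4Vectors::DataFrame] with `family`, `subfamily`, `count`.
#' @export
setGeneric("subfamilyCounts", function(x) standardGeneric("subfamilyCounts"))

#' Census totals
#' @param x a [CensusTable-class].
#' @return named list of totals (see [CensusTable-class]).
#' @export
setGeneric("censusTotals", function(x) standardGeneric("censusTotals"))

#' Presence/absence matrix values
#' @param x a [PresenceMatrix-class].
#' @return the numeric matrix over \{-3, 3\}.
#' @export
setGeneric("presenceValues", function(x) standardGeneric("presenceValues"))

#' Homolog calls of a pathway report
#' @param x a [PathwayReport-class].
#' @return a [S4Vectors::DataFrame] of calls.
#' @export
setGeneric("homologCalls", function(x) standardGeneric("homologCalls"))
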