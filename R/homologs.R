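# Verdict for one call given thresholds: failing any threshold by the
# band or more is absent; clearing all by the band or more is present;
# anything else is ambiguous. Zero thresholds carry no band (so
# degenerate thresholds accept everything).
.homologVerdict <- function(identity, similarity, coverPct, thr) {
  mins <- c(thr@idMin, thr@simMin, thr@covMin)
  vals <- c(identity, similarity, coverPct)
  margins <- vals - mins
  band <- ifelse(mins > 0, thr@ambiguousBand, 0)
  if (any(margins < 0 & margins <= -band)) return("absent")
  if (any(abs(margins) < band)) return("ambiguous")
  "present"
}

#' Find the best homolog of a reference protein in a proteome
#'
#' Local (Smith-Waterman) search of one reference enzyme against every
#' protein of a target proteome. The best target wins on score, then
#' percent identity, then input order. The verdict compares percent
#' identity, percent similarity ("homology") and query coverage
#' against [homologThresholds()]; calls within the ambiguity band of
#' any threshold are reported `ambiguous`.
#'
#' @param ref reference amino-acid sequence (string or `AAString`).
#' @param proteome a non-empty named [Biostrings::AAStringSet].
#' @param params an [AlignmentParams-class]; local mode by default.
#' @param thresholds a [HomologThresholds-class].
#' @param refId identifier recorded for the reference (default
#'   `"ref"`).
#' @return one-row [S4Vectors::DataFrame]: `ref_id`, `target_id`,
#'   `identity`, `similarity`, `query_cover`, `subject_cover`,
#'   `score`, `verdict`.
#' @examples
#' db <- generateReferenceDB(c("CYP202A1", "CYP153A1"), seed = 1)
#' prot <- refSequences(db)
#' bestHomolog(as.character(prot[["CYP202A1"]]), prot)
#' @export
bestHomolog <- function(ref, proteome,
                        params = alignmentParams("local"),
                        thresholds = homologThresholds(),
                        refId = "ref") {
  calls <- .allHomologCalls(ref, proteome, params, thresholds, refId)
  calls[1L, , drop = FALSE]
}

.allHomologCalls <- function(ref, proteome, params, thresholds, refId) {
  if (length(proteome) == 0L) stop("proteome must be non-empty")
  refc <- .checkProtein(ref, "reference")
  ids <- names(proteome) %||% paste0("protein", seq_along(proteome))
  rows <- lapply(seq_along(proteome), function(i) {
    r <- alignPair(refc, as.character(proteome[[i]]), params)
    idp <- percentIdentity(r)
    simp <- percentSimilarity(r)
    covq <- 100 * r@queryCover
    S4Vectors::DataFrame(
      ref_id = refId, target_id = ids[i],
      identity = idp, similarity = simp,
      query_cover = r@queryCover, subject_cover = r@subjectCover,
      score = r@score,
      verdict = .homologVerdict(idp, simp, covq, thresholds))
  })
  calls <- do.call(rbind, rows)
  ord <- order(-calls$score, -calls$identity, seq_len(nrow(calls)))
  calls[ord, , drop = FALSE]
}

#' Run a reference enzyme panel against a proteome
#'
#' For each enzyme of a reference pathway panel, searches the target
#' proteome for homologs and retains every call meeting the
#' thresholds (best first); the best call is always reported even when
#' `absent`, so the evidence against presence is visible. The pathway
#' is called present when every reference enzyme has at least one
#' `present` call.
#'
#' @param panel a named [Biostrings::AAStringSet] of reference enzymes,
#'   or a FASTA path; record names of the form `"gene_name|gene_id"`
#'   are split into the two fields.
#' @param proteome a named [Biostrings::AAStringSet] or FASTA path.
#' @param params an [AlignmentParams-class]; local mode by default.
#' @param thresholds a [HomologThresholds-class].
#' @return a [PathwayReport-class].
#' @examples
#' db <- generateReferenceDB(c("CYP202A1", "CYP153A1"), seed = 1)
#' prot <- refSequences(db)
#' runPathwayPanel(prot, prot)
#' @export
runPathwayPanel <- function(panel, proteome,
                            params = alignmentParams("local"),
                            thresholds = homologThresholds()) {
  if (is.character(panel) && length(panel) == 1L && file.exists(panel))
    panel <- Biostrings::readAAStringSet(panel)
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  if (length(proteome) == 0L) stop("proteome must be non-empty")
  pnames <- names(panel) %||% paste0("enzyme", seq_along(panel))
  gene <- sub("\\|.*$", "", pnames)
  gid <- ifelse(grepl("\\|", pnames), sub("^[^|]*\\|", "", pnames),
                NA_character_)
  blocks <- lapply(seq_along(panel), function(i) {
    calls <- .allHomologCalls(as.character(panel[[i]]), proteome, params,
                              thresholds, refId = gene[i])
    calls$gene_id <- gid[i]
    keep <- calls$verdict != "absent"
    keep[1L] <- TRUE  # best call always reported
    calls <- calls[keep, , drop = FALSE]
    calls$rank <- seq_len(nrow(calls))
    calls
  })
  calls <- do.call(rbind, blocks)
  present <- vapply(blocks, function(b) any(b$verdict == "present"),
                    logical(1))
  new("PathwayReport", calls = calls,
      nEnzymes = length(panel), nPresent = as.integer(sum(present)),
      pathwayPresent = all(present))
}

#' @rdname homologCalls
#' @export
setMethod("homologCalls", "PathwayReport", function(x) x@calls)

setMethod("show", "PathwayReport", function(object) {
  cat("PathwayReport:", object@nPresent, "of", object@nEnzymes,
      "enzymes present; pathway",
      if (object@pathwayPresent) "PRESENT" else "not present", "\n")
})

#' Write a pathway report to TSV
#'
#' @param report a [PathwayReport-class].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
exportPathwayReport <- function(report, path) {
  df <- as.data.frame(homologCalls(report))
  df$identity <- roundAsPrinted(df$identity, 0)
  df$similarity <- roundAsPrinted(df$similarity, 0)
  writeTsv(df[, c("ref_id", "gene_id", "target_id", "identity",
                  "similarity", "query_cover", "subject_cover",
                  "verdict", "rank")], path)
}
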