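#' Build a species-by-family presence/absence matrix
#'
#' One row per P450-containing species, one column per observed
#' family; presence is coded `3` and absence `-3` (the MeV heat-map
#' coding for P450 family profiles).
#'
#' @param x classification rows (as from [classifyProteome()]) or any
#'   data.frame with `species` and `family` columns; rows with `NA`
#'   family (short/rejected) are ignored.
#' @return a [PresenceMatrix-class] with identity orderings and no
#'   dendrograms (see [clusterMatrix()]).
#' @examples
#' pm <- buildPresenceMatrix(data.frame(
#'   species = c("a", "a", "b"), family = c("202", "153", "153")))
#' presenceValues(pm)
#' @export
buildPresenceMatrix <- function(x) {
  df <- as.data.frame(x)[, c("species", "family")]
  df <- df[!is.na(df$family) & !is.na(df$species), , drop = FALSE]
  if (nrow(df) == 0L) {
    m <- matrix(numeric(), 0L, 0L)
  } else {
    sp <- sort(unique(df$species))
    fam <- sort(unique(df$family))
    m <- matrix(-3, length(sp), length(fam), dimnames = list(sp, fam))
    m[cbind(match(df$species, sp), match(df$family, fam))] <- 3
  }
  new("PresenceMatrix", mat = m,
      rowOrder = seq_len(nrow(m)), colOrder = seq_len(ncol(m)),
      rowDend = NULL, colDend = NULL)
}

#' @rdname presenceValues
#' @export
setMethod("presenceValues", "PresenceMatrix", function(x) x@mat)

setMethod("dim", "PresenceMatrix", function(x) dim(x@mat))

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@mat), "species x", ncol(object@mat),
      "families;",
      if (is.null(object@rowDend)) "not clustered" else "clustered", "\n")
})

#' Hierarchically cluster a presence/absence matrix
#'
#' Agglomerative clustering of rows (species) and columns (families)
#' under the given distance metric (Euclidean by default, matching
#' MeV-style profile heat maps) and linkage (average by default).
#' Axes with fewer than two elements keep the identity ordering and no
#' dendrogram.
#'
#' @param x a [PresenceMatrix-class].
#' @param metric distance metric passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @param linkage agglomeration method passed to [stats::hclust()]:
#'   `"average"` (default), `"complete"` or `"single"`.
#' @return the matrix with `rowOrder`, `colOrder` and dendrograms set.
#' @examples
#' pm <- buildPresenceMatrix(data.frame(
#'   species = c("a", "a", "b", "c"),
#'   family = c("202", "153", "202", "108")))
#' clusterMatrix(pm)@rowOrder
#' @export
clusterMatrix <- function(x, metric = "euclidean",
                          linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  m <- x@mat
  if (nrow(m) >= 2L) {
    x@rowDend <- hclust(dist(m, method = metric), method = linkage)
    x@rowOrder <- x@rowDend$order
  }
  if (ncol(m) >= 2L) {
    x@colDend <- hclust(dist(t(m), method = metric), method = linkage)
    x@colOrder <- x@colDend$order
  }
  x
}

#' Co-presence counts of family pairs
#'
#' @param x a [PresenceMatrix-class].
#' @param families optional character vector; when given, returns the
#'   single count of species in which *all* of these families are
#'   present.
#' @return a symmetric family-by-family matrix of species counts, or a
#'   single count when `families` is given.
#' @examples
#' pm <- buildPresenceMatrix(data.frame(
#'   species = c("a", "a", "b", "b"),
#'   family = c("173", "202", "173", "202")))
#' coPresenceCounts(pm, c("173", "202"))
#' @export
coPresenceCounts <- function(x, families = NULL) {
  p <- x@mat == 3
  if (!is.null(families)) {
    missing <- setdiff(families, colnames(p))
    if (length(missing))
      stop("families not in matrix: ", paste(missing, collapse = ", "))
    return(sum(rowSums(p[, families, drop = FALSE]) == length(families)))
  }
  crossprod(p) * 1L
}

#' Export a presence/absence matrix to TSV
#'
#' Rows are species, columns families, cells -3/3; the first column
#' holds the species label. Round-trips through
#' [readPresenceMatrix()].
#'
#' @param x a [PresenceMatrix-class].
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
exportPresenceMatrix <- function(x, path) {
  df <- data.frame(species = rownames(x@mat), x@mat, check.names = FALSE)
  writeTsv(df, path)
}

#' Read a presence/absence matrix from TSV
#'
#' @param path TSV written by [exportPresenceMatrix()].
#' @return a [PresenceMatrix-class] (unclustered).
#' @export
readPresenceMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  new("PresenceMatrix", mat = m,
      rowOrder = seq_len(nrow(m)), colOrder = seq_len(ncol(m)),
      rowDend = NULL, colDend = NULL)
}

#' Export a clustering dendrogram in Newick format
#'
#' @param x a clustered [PresenceMatrix-class].
#' @param axis `"row"` (species) or `"column"` (families).
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(x, axis = c("row", "column"), path = NULL) {
  axis <- match.arg(axis)
  hc <- if (axis == "row") x@rowDend else x@colDend
  if (is.null(hc))
    stop("no ", axis, " dendrogram; run clusterMatrix() first")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
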