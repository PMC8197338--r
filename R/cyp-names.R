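#' Parse CYP nomenclature names
#'
#' Decomposes names such as `"CYP202A1"`, `"CYP107JE1"` or
#' `"CYP127A3v1"` into their nomenclature parts: the numeric family
#' token, the subfamily letter block (one or more uppercase letters, or
#' `"_"` for a family member with no assigned subfamily), the allele
#' number, and an optional `v<digits>` variant suffix. The family token
#' is kept as a character key: bacterial CYP families are pure numbers
#' and are never zero-padded.
#'
#' @param x character vector of names; each must start with `"CYP"`
#'   (case-insensitive).
#' @return a [S4Vectors::DataFrame] with columns `raw`, `family`,
#'   `subfamily`, `allele` (integer) and `variant` (`NA` when absent),
#'   one row per input name.
#' @seealso [formatCypName()] for the inverse.
#' @examples
#' parseCypName(c("CYP101D2", "CYP127A3v1", "CYP107JE1"))
#' @export
parseCypName <- function(x) {
  if (length(x) == 0L)
    return(S4Vectors::DataFrame(raw = character(), family = character(),
                                subfamily = character(), allele = integer(),
                                variant = character()))
  x <- as.character(x)
  rx <- "^[Cc][Yy][Pp]([0-9]+)([A-Z]+|_)([0-9]+)(v[0-9]+)?$"
  ok <- grepl(rx, x)
  if (any(!ok))
    stop("malformed CYP name(s): ", paste(x[!ok], collapse = ", "),
         " (expected CYP<family digits><subfamily letters or _>",
         "<allele digits>[v<digits>])")
  S4Vectors::DataFrame(
    raw = x,
    family = sub(rx, "\\1", x),
    subfamily = sub(rx, "\\2", x),
    allele = as.integer(sub(rx, "\\3", x)),
    variant = ifelse(nzchar(sub(rx, "\\4", x)), sub(rx, "\\4", x),
                     NA_character_)
  )
}

#' Format CYP nomenclature names
#'
#' Inverse of [parseCypName()]: assembles `CYP` + family + subfamily +
#' allele (+ variant).
#'
#' @param family character vector of numeric family tokens.
#' @param subfamily character vector of subfamily letter blocks (or `"_"`).
#' @param allele integer vector of allele numbers.
#' @param variant optional character vector of variant suffixes
#'   (`NA` for none).
#' @return character vector of names.
#' @examples
#' formatCypName("127", "A", 3, "v1")
#' @export
formatCypName <- function(family, subfamily, allele, variant = NA_character_) {
  v <- ifelse(is.na(variant), "", variant)
  paste0("CYP", family, subfamily, allele, v)
}

# Bijective base-26 subfamily letter sequence: 1 -> A, 26 -> Z,
# 27 -> AA, 28 -> AB, ...
subfamilyLetter <- function(i) {
  vapply(as.integer(i), function(k) {
    stopifnot(k >= 1L)
    s <- character()
    while (k > 0L) {
      r <- (k - 1L) %% 26L
      s <- c(LETTERS[r + 1L], s)
      k <- (k - 1L) %/% 26L
    }
    paste(s, collapse = "")
  }, character(1))
}
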