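#' @importFrom methods new validObject is slot
#' @importFrom stats dist hclust cophenetic
#' @importFrom utils read.delim write.table head data
NULL

# Twenty standard amino acids, in the fixed order used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background residue frequencies used by the synthetic generators
# (Robinson & Robinson-style composition, renormalised over the 20
# standard residues). Fixed constants: reproducibility over realism.
AA_BACKGROUND <- c(
  A = 0.0781, C = 0.0157, D = 0.0534, E = 0.0672, F = 0.0405,
  G = 0.0694, H = 0.0227, I = 0.0596, K = 0.0595, L = 0.0966,
  M = 0.0238, N = 0.0427, P = 0.0469, Q = 0.0393, R = 0.0541,
  S = 0.0683, T = 0.0541, V = 0.0687, W = 0.0110, Y = 0.0304
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Evaluate `expr` under a fixed RNG seed without disturbing the
# caller's RNG state. All generator randomness is routed through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Round the way printed tables round
#'
#' Rounds half away from zero at a fixed number of decimals (so 2.5
#' rounds to 3 and 8.009 to 8.01), which is how census summary tables
#' are conventionally printed; base R's `round()` uses banker's
#' rounding and cannot reproduce such tables. A `"truncate"` mode is
#' provided for tables whose final digit was evidently cut, not
#' rounded.
#'
#' @param x numeric vector.
#' @param decimals number of decimal places to keep.
#' @param mode `"half-away"` (default) or `"truncate"`.
#' @return numeric vector rounded as printed.
#' @examples
#' roundAsPrinted(8.009, 2)  # 8.01
#' roundAsPrinted(2.5, 0)    # 3
#' @export
roundAsPrinted <- function(x, decimals = 2, mode = c("half-away", "truncate")) {
  mode <- match.arg(mode)
  p <- 10^decimals
  switch(mode,
    "half-away" = sign(x) * floor(abs(x) * p + 0.5) / p,
    "truncate"  = sign(x) * floor(abs(x) * p + 1e-9) / p
  )
}
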