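# Independent alignment oracles: exhaustive enumeration of every
# monotone alignment path under affine gap costs (a gap of length k
# costs open + k * ext). Feasible only for tiny sequences; kept free
# of any package alignment code on purpose.

oracleGlobalScore <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A); n <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > m && j > n) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= m && j <= n) rec(i + 1L, j + 1L, 1L, sc + mat[A[i], B[j]])
    if (i <= m) rec(i + 1L, j, 2L, sc - ext - if (prev == 2L) 0 else open)
    if (j <= n) rec(i, j + 1L, 3L, sc - ext - if (prev == 3L) 0 else open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Local optimum = best global score over all substring pairs (an
# optimal local alignment has no terminal gaps, so substrings cover
# all cases); floored at 0 (the empty alignment).
oracleLocalScore <- function(a, b, mat, open = 11, ext = 1) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      s <- oracleGlobalScore(substr(a, i1, i2), substr(b, j1, j2),
                             mat, open, ext)
      if (s > best) best <- s
    }
  best
}

randomTestSeq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Small shared reference database: distinct families are independent
# random sequences, i.e. near background identity from one another.
makeTestDb <- function(names = c("CYP202A1", "CYP202B1", "CYP153A1"),
                       seed = 101, length = 350) {
  generateReferenceDB(names, seed = seed, length = length)
}
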