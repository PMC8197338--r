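writeBgcFixture <- function(rows, header = TRUE) {
  path <- tempfile(fileext = ".tsv")
  hdr <- paste("species", "region_id", "cluster_type", "contig",
               "start", "end", "most_similar_known_cluster",
               "similarity", sep = "\t")
  writeLines(c(if (header) hdr, rows), path)
  path
}

test_that("the simplified BGC table dialect parses", {
  path <- writeBgcFixture(c(
    "Celeribacter indicus\tregion01\tectoine\tchr1\t100\t5000\tEctoine, other\t100%",
    "Novosphingobium aromaticivorans\tregion02\tterpene\tchr1\t9000\t20000\tAstaxanthin dideoxyglycoside\t75%",
    "Beijerinckia indica\tregion03\tNRPS, T1PKS\tchr2\t50\t800\t-\t-"))
  r <- parseBgcTable(path)
  expect_equal(length(r), 3L)
  expect_equal(r$similarity[1], 100)
  expect_equal(r$similarity[2], 75)
  expect_true(is.na(r$similarity[3]))
  expect_true(is.na(r$most_similar_known_cluster[3]))
  expect_equal(GenomicRanges::start(r), c(100L, 9000L, 50L))
})

test_that("malformed coordinates error; unknown columns warn", {
  bad <- writeBgcFixture(
    "Sp x\tregion01\tterpene\tchr1\t5000\t100\t-\t-")
  expect_error(parseBgcTable(bad), "start > end")
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "species\tregion_id\tcluster_type\tcontig\tstart\tend\tbogus",
    "Sp x\tregion01\tterpene\tchr1\t100\t5000\tzzz"), path)
  expect_warning(r <- parseBgcTable(path), "bogus")
  expect_equal(length(r), 1L)
})

test_that("membership requires full containment on the same contig", {
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 50000),
    species = "Sp x", region_id = "r1", cluster_type = "terpene",
    most_similar_known_cluster = NA_character_, similarity = NA_real_)
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(100, 49000, 60000, 100),
                     end = c(1300, 51000, 61000, 1300)),
    strand = "+",
    gene_id = c("inside", "straddle", "outside", "other_contig"),
    is_p450 = TRUE,
    cyp_name = c("CYP206A1", "CYP206A2", "CYP206A3", "CYP206A4"))
  m <- as.data.frame(p450sInBgcs(genes, regions))
  expect_equal(m$gene_id, "inside")
  expect_equal(m$cluster_type, "terpene")
  # enlarging the region never removes members
  bigger <- regions
  GenomicRanges::end(bigger) <- 52000
  m2 <- as.data.frame(p450sInBgcs(genes, bigger))
  expect_true(all(m$gene_id %in% m2$gene_id))
  expect_equal(sort(m2$gene_id), c("inside", "straddle"))
})

test_that("planted synthetic membership is recovered exactly", {
  g <- generateGenomeWithBgcs(12, 2, 3, seed = 5)
  m <- as.data.frame(p450sInBgcs(g$genes, g$regions))
  expect_equal(sort(m$gene_id), sort(g$truth))
  g0 <- generateGenomeWithBgcs(12, 0, 0, seed = 6)
  expect_equal(nrow(as.data.frame(
    p450sInBgcs(g0$genes, g0$regions))), 0L)
})

test_that("cluster-type tallies split hybrid labels", {
  expect_equal(tallyClusterTypes(c("terpene", "terpene", "NRPS")),
               c(terpene = 2L, NRPS = 1L))
  expect_equal(length(tallyClusterTypes(character())), 0L)
  t2 <- tallyClusterTypes(c("hserlactone, t2pks", "t2pks"))
  expect_equal(unname(t2["t2pks"]), 2L)
  expect_equal(unname(t2["hserlactone"]), 1L)
  # sum of per-type counts equals sum of per-region label multiplicity
  labels <- c("terpene", "NRPS, T1PKS", "T1PKS")
  expect_equal(sum(tallyClusterTypes(labels)),
               sum(lengths(strsplit(labels, ",\\s*"))))
})

test_that("the BGC summary mirrors the census percentage formula", {
  m <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3"),
    cyp_name = c("CYP1326A2", "CYP195A21", "CYP2334A1"),
    species = "Sulfitobacter sp. AM1-D1",
    region_id = c("r1", "r2", "r3"),
    cluster_type = c("acyl_amino_acids", "bacteriocin", "NRPS-like"),
    most_similar_known_cluster = NA_character_,
    similarity = NA_real_)
  s <- bgcSummary(m, nP450s = 874)
  expect_equal(s$nMembers, 3L)
  expect_equal(s$nSpecies, 1L)
  expect_equal(s$percentage, bgcPercentage(3, 874))
  expect_equal(unname(s$perFamily[c("1326", "195", "2334")]),
               c(1L, 1L, 1L))
  s0 <- bgcSummary(m[0, ], nP450s = 874)
  expect_equal(s0$percentage, 0)
})
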