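presenceFixture <- function() {
  # rows: r1 = (3, 3, -3), r2 = (3, -3, -3), r3 = (-3, -3, 3)
  buildPresenceMatrix(data.frame(
    species = c("r1", "r1", "r2", "r3"),
    family = c("f1", "f2", "f1", "f3")))
}

test_that("presence coding is 3/-3 over observed families only", {
  pm <- buildPresenceMatrix(data.frame(
    species = "Sp one", family = c("202", "153")))
  m <- presenceValues(pm)
  expect_equal(dim(m), c(1L, 2L))
  expect_true(all(m == 3))
  pm2 <- presenceFixture()
  expect_equal(unname(presenceValues(pm2)["r1", ]), c(3, 3, -3))
  # no all-absent column can exist by construction
  expect_true(all(colSums(presenceValues(pm2) == 3) >= 1))
  # empty census -> empty matrix
  expect_equal(dim(buildPresenceMatrix(
    data.frame(species = character(), family = character()))),
    c(0L, 0L))
})

test_that("first merge follows hand-computed Euclidean distances", {
  pm <- presenceFixture()
  m <- presenceValues(pm)
  d <- dist(m)
  # hand check: r1/r2 differ in one coordinate -> 6; r1/r3 in all
  # three -> sqrt(108); r2/r3 in two -> sqrt(72); 6 is the minimum
  expect_equal(as.numeric(d), c(6, sqrt(108), sqrt(72)))
  cl <- clusterMatrix(pm)
  expect_equal(sort(cl@rowDend$merge[1, ]), c(-2L, -1L))
  expect_equal(cl@rowDend$height[1], 6)
})

test_that("identical rows merge at distance zero", {
  pm <- buildPresenceMatrix(data.frame(
    species = c("a", "a", "b", "b", "c"),
    family = c("f1", "f2", "f1", "f2", "f3")))
  cl <- clusterMatrix(pm)
  expect_equal(cl@rowDend$height[1], 0)
  expect_equal(sort(cl@rowDend$merge[1, ]), c(-2L, -1L))
})

test_that("row permutation leaves the dendrogram topology unchanged", {
  df <- data.frame(
    species = rep(c("s1", "s2", "s3", "s4"), times = c(2, 2, 1, 3)),
    family = c("f1", "f2", "f1", "f3", "f2", "f1", "f2", "f3"))
  pm1 <- clusterMatrix(buildPresenceMatrix(df))
  pm2 <- clusterMatrix(buildPresenceMatrix(df[rev(seq_len(nrow(df))), ]))
  # species labels sort identically, so matrices and trees agree
  expect_identical(presenceValues(pm1), presenceValues(pm2))
  c1 <- cophenetic(pm1@rowDend); c2 <- cophenetic(pm2@rowDend)
  expect_equal(as.matrix(c1), as.matrix(c2))
})

test_that("cophenetic heights are non-negative and monotone", {
  set.seed(7)
  df <- data.frame(
    species = sample(paste0("s", 1:8), 30, replace = TRUE),
    family = sample(paste0("f", 1:6), 30, replace = TRUE))
  pm <- clusterMatrix(buildPresenceMatrix(unique(df)))
  h <- pm@rowDend$height
  expect_true(all(h >= 0))
  expect_true(all(diff(h) >= -1e-9))
})

test_that("single-axis matrices keep identity order, no dendrogram", {
  pm <- buildPresenceMatrix(data.frame(species = "only",
                                       family = c("f1", "f2")))
  cl <- clusterMatrix(pm)
  expect_equal(cl@rowOrder, 1L)
  expect_null(cl@rowDend)
  expect_false(is.null(cl@colDend))
})

test_that("co-presence counts planted pairs", {
  df <- rbind(
    data.frame(species = paste0("s", 1:7), family = "173"),
    data.frame(species = paste0("s", 1:7), family = "202"),
    data.frame(species = paste0("s", 8:10), family = "173"))
  pm <- buildPresenceMatrix(df)
  expect_equal(coPresenceCounts(pm, c("173", "202")), 7L)
  cc <- coPresenceCounts(pm)
  expect_equal(cc["173", "202"], 7L)
  expect_equal(cc["173", "173"], 10L)
  # disjoint columns count zero
  pm2 <- buildPresenceMatrix(data.frame(species = c("a", "b"),
                                        family = c("f1", "f2")))
  expect_equal(coPresenceCounts(pm2, c("f1", "f2")), 0L)
})

test_that("matrix coding round-trips through TSV and Newick exports", {
  pm <- clusterMatrix(presenceFixture())
  tf <- tempfile(fileext = ".tsv")
  exportPresenceMatrix(pm, tf)
  back <- readPresenceMatrix(tf)
  expect_identical(presenceValues(back), presenceValues(pm))
  nwk <- dendrogramNewick(pm, "row")
  expect_match(nwk, "^\\(")
  expect_true(all(c("r1", "r2", "r3") %in%
                    ape::read.tree(text = nwk)$tip.label))
})
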