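panelFixture <- function(n = 3, seed = 301, length = 320) {
  seqs <- vapply(seq_len(n) + seed, function(s) randomProtein(length, s),
                 character(1))
  names(seqs) <- sprintf("enz%d|GID%03d", seq_len(n), seq_len(n))
  Biostrings::AAStringSet(seqs)
}

test_that("self-search returns 100% identity and a present verdict", {
  panel <- panelFixture()
  proteome <- panel
  names(proteome) <- sprintf("target%d", seq_along(proteome))
  call <- bestHomolog(as.character(panel[[1]]), proteome,
                      refId = "enz1")
  expect_equal(call$identity, 100)
  expect_equal(call$similarity, 100)
  expect_equal(call$target_id, "target1")
  expect_equal(call$verdict, "present")
})

test_that("random decoys sit at chance identity and are absent", {
  ref <- randomProtein(400, 311)
  decoys <- Biostrings::AAStringSet(vapply(
    312:316, function(s) randomProtein(400, s), character(1)))
  names(decoys) <- paste0("decoy", 1:5)
  call <- bestHomolog(ref, decoys)
  # local alignments of unrelated proteins cover only short spans at
  # modest identity; the coverage threshold rejects them
  expect_lt(call$query_cover, 0.5)
  expect_lt(call$identity, 50)
  expect_equal(call$verdict, "absent")
})

test_that("a 39% mutant is found with homology above identity", {
  ref <- randomProtein(400, 321)
  mut <- mutateToIdentity(ref, 0.39, 322)
  proteome <- Biostrings::AAStringSet(c(
    hit = mut, decoy = randomProtein(400, 323)))
  call <- bestHomolog(ref, proteome)
  expect_equal(call$target_id, "hit")
  expect_equal(call$identity, 39, tolerance = 0.05)
  expect_gt(call$similarity, call$identity)
})

test_that("zero thresholds accept anything; verdicts band correctly", {
  ref <- randomProtein(300, 331)
  proteome <- Biostrings::AAStringSet(c(x = randomProtein(300, 332)))
  zero <- homologThresholds(0, 0, 0)
  expect_equal(bestHomolog(ref, proteome, thresholds = zero)$verdict,
               "present")
  # within two points of a threshold -> ambiguous
  expect_equal(cypcensus:::.homologVerdict(26, 60, 80,
                                           homologThresholds()),
               "ambiguous")
  expect_equal(cypcensus:::.homologVerdict(40, 60, 80,
                                           homologThresholds()),
               "present")
  expect_equal(cypcensus:::.homologVerdict(10, 60, 80,
                                           homologThresholds()),
               "absent")
  expect_error(bestHomolog(ref, Biostrings::AAStringSet()),
               "non-empty")
})

test_that("calls are stable under proteome reordering", {
  panel <- panelFixture(2)
  targets <- Biostrings::AAStringSet(c(
    t1 = mutateToIdentity(as.character(panel[[1]]), 0.6, 341),
    t2 = randomProtein(320, 342),
    t3 = mutateToIdentity(as.character(panel[[2]]), 0.7, 343)))
  r1 <- runPathwayPanel(panel, targets)
  r2 <- runPathwayPanel(panel, targets[c(3, 1, 2)])
  c1 <- as.data.frame(homologCalls(r1))
  c2 <- as.data.frame(homologCalls(r2))
  expect_equal(c1[order(c1$ref_id, c1$rank),
                  c("ref_id", "target_id", "identity", "verdict")],
               c2[order(c2$ref_id, c2$rank),
                  c("ref_id", "target_id", "identity", "verdict")],
               ignore_attr = TRUE)
})

test_that("pathway verdict needs every enzyme present; duplicates
           give multiple calls", {
  panel <- panelFixture(3)
  # plant homologs for enzymes 1 and 2; enzyme 2 twice (fadD36-style)
  targets <- Biostrings::AAStringSet(c(
    h1 = mutateToIdentity(as.character(panel[[1]]), 0.60, 351),
    h2a = mutateToIdentity(as.character(panel[[2]]), 0.60, 352),
    h2b = mutateToIdentity(as.character(panel[[2]]), 0.55, 353),
    noise = randomProtein(320, 354)))
  rep1 <- runPathwayPanel(panel, targets)
  expect_equal(rep1@nEnzymes, 3L)
  expect_equal(rep1@nPresent, 2L)
  expect_false(rep1@pathwayPresent)
  calls <- as.data.frame(homologCalls(rep1))
  enz2 <- calls[calls$ref_id == "enz2" & calls$verdict == "present", ]
  expect_equal(sort(enz2$target_id), c("h2a", "h2b"))
  expect_equal(calls$gene_id[calls$ref_id == "enz2"][1], "GID002")
  # complete panel -> pathway present
  full <- Biostrings::AAStringSet(c(
    as.character(targets),
    h3 = mutateToIdentity(as.character(panel[[3]]), 0.60, 355)))
  rep2 <- runPathwayPanel(panel, full)
  expect_true(rep2@pathwayPresent)
  expect_equal(rep2@nPresent, 3L)
})
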