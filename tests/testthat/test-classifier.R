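test_that("identity bands map onto nomenclature verdicts", {
  db <- makeTestDb()
  ref <- as.character(refSequences(db)[["CYP202A1"]])

  exact <- classifyProtein(ref, "q1", db)
  expect_equal(exact$status, "existing_subfamily")
  expect_equal(exact$family, "202")
  expect_equal(exact$subfamily, "A")
  expect_equal(exact$assigned_name, "CYP202A2")

  mid <- classifyProtein(mutateToIdentity(ref, 0.50, 41), "q2", db)
  expect_equal(mid$status, "new_subfamily")
  expect_equal(mid$family, "202")
  expect_equal(mid$subfamily, "C")  # A and B are taken

  far <- classifyProtein(mutateToIdentity(ref, 0.20, 42), "q3", db)
  expect_equal(far$status, "new_family")
  expect_equal(far$family, "203")  # allocated above max observed
  expect_equal(far$subfamily, "A")
  expect_true(far$provisional)
})

test_that("boundary identities fall to the lower band under strict rule", {
  db <- generateReferenceDB("CYP300A1", seed = 51, length = 100)
  ref <- as.character(refSequences(db)[["CYP300A1"]])
  q40 <- mutateToIdentity(ref, 0.40, 52)  # exactly 40/100 identical
  thr <- classifierThresholds(shortMinLength = 50)
  row <- classifyProtein(q40, "q", db, thr)
  expect_equal(row$best_identity, 40)
  expect_equal(row$status, "new_family")
  # inclusive semantics flips the same query to the family band
  thrIncl <- classifierThresholds(shortMinLength = 50, strict = FALSE)
  expect_equal(classifyProtein(q40, "q", db, thrIncl)$status,
               "new_subfamily")
  q55 <- mutateToIdentity(ref, 0.55, 53)
  expect_equal(classifyProtein(q55, "q", db, thr)$status,
               "new_subfamily")
  expect_equal(classifyProtein(q55, "q", db, thrIncl)$status,
               "existing_subfamily")
})

test_that("short candidates are flagged and take no name", {
  db <- makeTestDb()
  frag <- substr(as.character(refSequences(db)[[1]]), 1, 200)
  row <- classifyProtein(frag, "frag", db)
  expect_equal(row$status, "short")
  expect_true(is.na(row$assigned_name))
})

test_that("a proteome classifies sequentially with truth recovery", {
  db <- makeTestDb()
  targets <- data.frame(ref = "CYP153A1",
                        identity = c(1.0, 0.9, 0.5, 0.3, 0.2))
  sp <- generateSpecies(speciesSpec("Phenylobacterium zucineum",
                                    targets, seed = 61), db)
  run <- classifyProteome(sp$proteome, "Phenylobacterium zucineum", db)
  expect_equal(run$results$status,
               c("existing_subfamily", "existing_subfamily",
                 "new_subfamily", "new_family", "new_family"))
  expect_equal(run$results$species,
               rep("Phenylobacterium zucineum", 5))
  # the two distant queries founded distinct new families
  newFams <- run$results$family[run$results$status == "new_family"]
  expect_equal(length(unique(newFams)), 2L)
  # allocated names became part of the database
  expect_equal(length(run$db), length(db) + 5L)
})

test_that("reclassifying an assigned sequence returns its own name", {
  db <- makeTestDb()
  q <- mutateToIdentity(as.character(refSequences(db)[[1]]), 0.5, 71)
  run <- classifyProteome(Biostrings::AAStringSet(c(newq = q)),
                          "Sp x", db)
  again <- classifyProtein(q, "newq2", run$db)
  expect_equal(again$best_hit, run$results$assigned_name)
  expect_equal(again$best_identity, 100)
  expect_equal(again$family, run$results$family)
})

test_that("family-size multiset is order-invariant away from the
           threshold band", {
  db <- makeTestDb()
  refs <- refNames(db)$raw
  targets <- data.frame(ref = rep(refs, each = 2),
                        identity = rep(c(0.85, 0.30), times = 3))
  sp <- generateSpecies(speciesSpec("Sp y", targets, seed = 81), db)
  run1 <- classifyProteome(sp$proteome, "Sp y", db)
  perm <- rev(seq_along(sp$proteome))
  run2 <- classifyProteome(sp$proteome[perm], "Sp y", db)
  sizes <- function(r) sort(table(r$results$status))
  expect_equal(sizes(run1), sizes(run2))
  expect_equal(sort(table(run1$results$family[
    run1$results$status != "new_family"])),
    sort(table(run2$results$family[
      run2$results$status != "new_family"])))
})

test_that("duplicate query ids are rejected", {
  db <- makeTestDb()
  aa <- Biostrings::AAStringSet(c(a = randomProtein(350, 91),
                                  a = randomProtein(350, 92)))
  expect_error(classifyProteome(aa, "Sp z", db), "duplicate")
})

test_that("the heme-motif screen finds motifs, tolerates one mismatch", {
  expect_true(screenCandidate("AAAFAAGAAACAGAAA"))     # exact FxxGxxxCxG
  expect_true(screenCandidate("AAAFAAGAAACAAAAA"))     # one mismatch (G->A)
  expect_false(screenCandidate("AAAFAAAAAACAAAAA"))    # two mismatches
  expect_false(screenCandidate(randomProtein(9, 1)))   # shorter than motif
  # screening off (the default) classifies everything
  db <- makeTestDb()
  run <- classifyProteome(Biostrings::AAStringSet(
    c(d = randomProtein(400, 93))), "Sp w", db, screen = FALSE)
  expect_false("rejected" %in% run$results$status)
})
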