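test_that("census aggregation counts families, subfamilies, species", {
  res <- S4Vectors::DataFrame(
    query = c("a", "b", "c", "d"),
    species = c("Sp one", "Sp one", "Sp two", "Sp two"),
    family = c("202", "202", "153", NA),
    subfamily = c("A", "A", "A", NA),
    status = c("existing_subfamily", "existing_subfamily",
               "new_subfamily", "short"))
  roster <- data.frame(species = c("Sp one", "Sp two", "Sp three"))
  ct <- buildCensus(res, roster)
  tot <- censusTotals(ct)
  expect_equal(tot$nP450s, 3L)
  expect_equal(tot$nFamilies, 2L)
  expect_equal(tot$nSubfamilies, 2L)
  expect_equal(tot$nShort, 1L)
  expect_equal(tot$nSpeciesAnalyzed, 3L)
  expect_equal(tot$nSpeciesWithP450s, 2L)
  ft <- familyCounts(ct)
  expect_equal(ft$percentage[ft$family == "202"], 100 * 2 / 3)
  # conservation invariants
  expect_equal(sum(ft$count), tot$nP450s)
  expect_equal(sum(ft$percentage), 100)
})

test_that("empty results give an all-zero census", {
  ct <- buildCensus(cypcensus:::.emptyClassificationRow(),
                    data.frame(species = "Sp one"))
  expect_equal(censusTotals(ct)$nP450s, 0L)
  expect_equal(nrow(familyCounts(ct)), 0L)
})

test_that("species absent from the roster are an error", {
  res <- S4Vectors::DataFrame(query = "a", species = "Ghost sp",
                              family = "202", subfamily = "A",
                              status = "existing_subfamily")
  expect_error(buildCensus(res, data.frame(species = "Sp one")), "Ghost")
})

test_that("summary statistics follow their defining quotients", {
  expect_equal(averageP450s(874, 241), 874 / 241, tolerance = 1e-12)
  expect_equal(averageP450s(0, 10), 0)
  expect_error(averageP450s(1, 0), "> 0")
  expect_equal(diversityPercentage(1, 1, 1), 100)
  expect_equal(roundAsPrinted(diversityPercentage(143, 874, 241), 4),
               0.0679)
  # homogeneity: doubling the P450 count halves the diversity
  expect_equal(diversityPercentage(36, 2 * 341, 114),
               diversityPercentage(36, 341, 114) / 2)
  expect_equal(bgcPercentage(0, 500), 0)
  expect_equal(roundAsPrinted(bgcPercentage(21, 874), 2), 2.40)
})

test_that("printed-table rounding is half away from zero", {
  expect_equal(roundAsPrinted(0.0679, 2), 0.07)
  expect_equal(roundAsPrinted(8.009, 2), 8.01)
  expect_equal(roundAsPrinted(2.5, 0), 3)
  expect_equal(roundAsPrinted(-2.5, 0), -3)
  expect_equal(roundAsPrinted(22.545, 0), 23)
  expect_equal(roundAsPrinted(0.0085864, 3, mode = "truncate"), 0.008)
})

test_that("family-set comparison yields exact Venn regions", {
  cmp <- compareFamilySets(list(A = c("107", "125"), B = "107",
                                C = c("107", "152")))
  expect_equal(cmp$universal, "107")
  expect_equal(cmp$pairwise["A", "C"], 1L)
  regions <- setNames(cmp$regions$count, cmp$regions$taxa)
  expect_equal(unname(regions["A"]), 1L)        # 125 is A-only
  expect_equal(cmp$regions$families[cmp$regions$taxa == "A"], "125")
  expect_equal(unname(regions["A&B&C"]), 1L)
  expect_equal(unname(regions["A&B"]), 0L)
  # five disjoint singletons share nothing
  cmp5 <- compareFamilySets(list(a = "1", b = "2", c = "3", d = "4",
                                 e = "5"))
  expect_equal(length(cmp5$universal), 0L)
  # sets built from two synthetic taxa sharing four families
  t1 <- c("101", "102", "103", "104", "105", "106")
  t2 <- c("103", "104", "105", "106", "201")
  cmp2 <- compareFamilySets(list(tax1 = t1, tax2 = t2))
  expect_equal(cmp2$pairwise["tax1", "tax2"], 4L)
})

test_that("a printed-style census TSV parses with carried-forward
           families", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "family\tfamily_count\tpercentage\tsubfamily\tsubfamily_count",
    "CYP101\t3\t60.00%\tB\t1",
    "\t\t\tC\t2",
    "CYP107\t2\t40.00%\tAN\t1",
    "\t\t\t_\t1"), path)
  ct <- readFamilyCensus(path)
  tot <- censusTotals(ct)
  expect_equal(tot$nP450s, 5L)
  expect_equal(tot$nFamilies, 2L)
  expect_equal(tot$nSubfamilies, 3L)  # "_" is not a subfamily
  expect_equal(subfamilyCounts(ct)$count[
    subfamilyCounts(ct)$subfamily == "C"], 2L)
})
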