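writeLinesTo <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("transaction reading collapses duplicates and keys by prescription", {
  f <- writeLinesTo(c("prescription_id,herb_id,route",
                      "p1,A,internal", "p1,B,internal", "p2,A,internal"))
  corp <- readTransactions(f)
  expect_equal(nPrescriptions(corp), 2L)
  expect_equal(herbSets(corp)$p1, c("A", "B"))
  expect_equal(herbSets(corp)$p2, "A")

  fdup <- writeLinesTo(c("prescription_id,herb_id,route",
                         "p1,A,internal", "p1,A,internal"))
  expect_warning(corp2 <- readTransactions(fdup), "collapsed")
  expect_equal(herbSets(corp2)$p1, "A")
})

test_that("transaction reading rejects malformed input", {
  bad <- writeLinesTo(c("prescription_id,herb_id,route", "p1,A,topical"))
  expect_error(readTransactions(bad), "unknown route")
  conflict <- writeLinesTo(c("prescription_id,herb_id,route",
                             "p1,A,internal", "p1,B,external"))
  expect_error(readTransactions(conflict), "conflicting route")
  empty <- writeLinesTo("prescription_id,herb_id,route")
  expect_error(readTransactions(empty), "empty")
  expect_error(readTransactions(tempfile()), "not found")
})

test_that("row order never affects the corpus and round-trips are exact", {
  rows <- c("p1,A,internal", "p1,B,internal", "p2,C,external",
            "p3,A,internal", "p3,C,internal", "p3,D,internal")
  f1 <- writeLinesTo(c("prescription_id,herb_id,route", rows))
  f2 <- writeLinesTo(c("prescription_id,herb_id,route", rev(rows)))
  c1 <- readTransactions(f1)
  c2 <- readTransactions(f2)
  expect_equal(herbSets(c1), herbSets(c2))
  expect_equal(prescriptionRoutes(c1), prescriptionRoutes(c2))

  out <- withr::local_tempfile(fileext = ".tsv")
  writeTransactions(c1, out)
  c3 <- readTransactions(out)      # TSV autodetected
  expect_equal(nPrescriptions(c3), nPrescriptions(c1))
  expect_equal(herbSets(c3), herbSets(c1))
  expect_equal(prescriptionRoutes(c3), prescriptionRoutes(c1))
})

test_that("annotation reading decodes meridian flags into the canonical set", {
  f <- writeLinesTo(c(
    "herb_id,latin_name,category,LR,HT,PC,SP,LU,KI,GB,SI,TE,ST,LI,BL",
    "Polygonum,Polygonum multiflorum Thunb.,17,Y,,,,,Y,,,,,,",
    "Glycyrrhiza,Glycyrrhiza uralensis Fisch.,8,,,,,,,,,,,,"))
  ann <- readAnnotations(f)
  expect_equal(MERIDIANS[unlist(ann[ann$herb_id == "Polygonum", MERIDIANS])],
               c("LR", "KI"))
  expect_false(any(unlist(ann[ann$herb_id == "Glycyrrhiza", MERIDIANS])))
  expect_equal(ann$category, c(17L, 8L))
})

test_that("annotation reading enforces key uniqueness and valid columns", {
  dup <- writeLinesTo(c("herb_id,latin_name,category,LR",
                        "A,Herba A,1,Y", "A,Herba A,2,"))
  expect_error(readAnnotations(dup), "duplicate herb_id")
  badcat <- writeLinesTo(c("herb_id,latin_name,category,LR",
                           "A,Herba A,21,Y"))
  expect_error(readAnnotations(badcat), "category")
  badcol <- writeLinesTo(c("herb_id,latin_name,category,XX",
                           "A,Herba A,1,Y"))
  expect_error(readAnnotations(badcol), "unknown meridian")
})

test_that("annotation round-trip preserves flags and categories", {
  sets <- list(A = c("LR", "KI"), B = character(0), C = MERIDIANS)
  ann <- makeAnnotations(sets, category = c(17L, 8L, 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(ann, f)
  back <- readAnnotations(f)
  expect_equal(back[order(back$herb_id), ], ann[order(ann$herb_id), ],
               ignore_attr = TRUE)
})

test_that("route filtering partitions the corpus and keeps herb sets intact", {
  sets <- c(lapply(1:7, function(i) c("A", paste0("h", i))),
            lapply(1:4, function(i) c("B", paste0("g", i))))
  names(sets) <- paste0("p", seq_along(sets))
  corp <- herbCorpus(sets, route = rep(c("internal", "external"),
                                       c(7L, 4L)))
  int <- filterByRoute(corp, "internal")
  ext <- filterByRoute(corp, "external")
  expect_equal(nPrescriptions(int), 7L)
  expect_equal(nPrescriptions(ext), 4L)
  expect_equal(nPrescriptions(int) + nPrescriptions(ext),
               nPrescriptions(corp))
  expect_equal(herbSets(int), herbSets(corp)[1:7])
  expect_error(filterByRoute(corp, "topical"), "route")

  none <- filterByRoute(filterByRoute(corp, "internal"), "external")
  expect_equal(nPrescriptions(none), 0L)
})

test_that("fixture corpora realise specified counts exactly", {
  spec <- countSpec(312, c(Angelica = 171, Polygonum = 175),
                    c("Angelica+Polygonum" = 120))
  corp <- buildFixtureCorpus(spec)
  sets <- herbSets(corp)
  expect_equal(nPrescriptions(corp), 312L)
  expect_equal(bruteItemsetCount(sets, "Angelica"), 171L)
  expect_equal(bruteItemsetCount(sets, "Polygonum"), 175L)
  expect_equal(bruteItemsetCount(sets, c("Angelica", "Polygonum")), 120L)

  # disjoint pair: joint constrained to zero
  corp0 <- buildFixtureCorpus(countSpec(4, c(A = 2, B = 2),
                                        c("A+B" = 0)))
  sets0 <- herbSets(corp0)
  expect_equal(bruteItemsetCount(sets0, c("A", "B")), 0L)
  expect_equal(bruteItemsetCount(sets0, "A"), 2L)
  expect_equal(bruteItemsetCount(sets0, "B"), 2L)
})

test_that("triple fixtures satisfy nested pair and marginal constraints", {
  spec <- countSpec(312, c(L = 132, P = 175, A = 171),
                    c("L+P" = 82, "A+L" = 107, "A+P" = 120,
                      "A+L+P" = 73))
  corp <- buildFixtureCorpus(spec)
  sets <- herbSets(corp)
  expect_equal(bruteItemsetCount(sets, c("A", "L", "P")), 73L)
  expect_equal(bruteItemsetCount(sets, c("L", "P")), 82L)
  expect_equal(bruteItemsetCount(sets, c("A", "L")), 107L)
  expect_equal(bruteItemsetCount(sets, c("A", "P")), 120L)
  expect_equal(bruteItemsetCount(sets, "L"), 132L)
  expect_equal(bruteItemsetCount(sets, "P"), 175L)
  expect_equal(bruteItemsetCount(sets, "A"), 171L)
  expect_equal(nPrescriptions(corp), 312L)
})

test_that("fixture construction is deterministic and policies pad correctly", {
  spec <- countSpec(10, c(A = 3, B = 3), c("A+B" = 1))
  c1 <- buildFixtureCorpus(spec)
  c2 <- buildFixtureCorpus(spec)
  expect_identical(herbSets(c1), herbSets(c2))
  dummies <- grep("^DUMMY_", herbUniverse(c1), value = TRUE)
  expect_equal(length(dummies), 10L - (1L + 2L + 2L))
  cpad <- buildFixtureCorpus(spec, fillerPolicy = "empty_pad")
  expect_true("PLACEBO" %in% herbUniverse(cpad))
  expect_equal(bruteItemsetCount(herbSets(cpad), "PLACEBO"), 5L)
  expect_true(all(lengths(herbSets(cpad)) >= 1L))
})

test_that("infeasible count specs are rejected", {
  expect_error(countSpec(10, c(A = 3, B = 3), c("A+B" = 5)),
               "infeasible")
  expect_error(countSpec(10, c(A = -1)), "negative")
  expect_error(buildFixtureCorpus(countSpec(5, c(A = 4, B = 4),
                                            c("A+B" = 1))),
               "infeasible")
  # triple cover exceeding a contained pair
  expect_error(buildFixtureCorpus(countSpec(20, integer(0),
                                            c("A+B" = 2, "A+B+C" = 5))),
               "over-covered")
})
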