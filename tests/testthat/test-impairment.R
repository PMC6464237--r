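interactorFixture <- function() {
  data.frame(name = c("I1", "I2", "I3", "I4"),
             uniprot = paste0("P0000", 1:4),
             binding_residues = I(list(60:70, 100:110, c(5:10, 150:160),
                                       200:210)),
             stringsAsFactors = FALSE)
}

test_that("interval membership decides affected vs unaffected", {
  ms <- MutationSet(variant = c("p.Ala65Val", "p.Ala150Val"),
                    position = c(65L, 150L), wt_aa = "A", mut_aa = "V",
                    n_patients = c(1L, 1L),
                    phenotypes = list("pheochromocytoma", "pheochromocytoma"))
  un <- unaffectedInteractors("pheochromocytoma", ms, interactorFixture())
  expect_equal(as.character(un), c("I2", "I4"))
  expect_false(attr(un, "vacuous"))
})

test_that("zero mutations leave every interactor unaffected with a vacuous flag", {
  ms <- tinyMutations()[integer()]
  un <- unaffectedInteractors("elst", ms, interactorFixture())
  expect_equal(as.character(un), c("I1", "I2", "I3", "I4"))
  expect_true(attr(un, "vacuous"))
})

test_that("a positional margin widens the affected halo", {
  ms <- MutationSet("p.Ala71Val", 71L, "A", "V", 1L,
                    phenotypes = list("pheochromocytoma"))
  un0 <- unaffectedInteractors("pheochromocytoma", ms, interactorFixture(),
                               margin = 0L)
  un1 <- unaffectedInteractors("pheochromocytoma", ms, interactorFixture(),
                               margin = 1L)
  expect_true("I1" %in% un0)
  expect_false("I1" %in% un1)
})

test_that("the impairment matrix matches a hand-built truth table", {
  ms <- MutationSet(
    variant = sprintf("p.Ala%dVal", c(65, 105, 8, 205, 150)),
    position = c(65L, 105L, 8L, 205L, 150L), wt_aa = "A", mut_aa = "V",
    n_patients = rep(1L, 5),
    phenotypes = list("renal_disease", "renal_disease",
                      "pheochromocytoma", "polycythemia",
                      c("renal_disease", "pheochromocytoma")))  # multi: dropped
  im <- buildImpairmentMatrix(ms, interactorFixture())
  m <- impairmentCells(im)
  # renal: positions {65,105} -> I1, I2 affected
  expect_equal(unname(m["renal_disease", ]),
               c("affected", "affected", "unaffected", "unaffected"))
  # pheochromocytoma: {8} -> I3 affected
  expect_equal(unname(m["pheochromocytoma", ]),
               c("unaffected", "unaffected", "affected", "unaffected"))
  # polycythemia: {205} -> I4 affected
  expect_equal(unname(m["polycythemia", ]),
               c("unaffected", "unaffected", "unaffected", "affected"))
  expect_equal(colnames(m), c("I1", "I2", "I3", "I4"))  # alphabetical
})

test_that("adding a mutation never flips a cell back to unaffected", {
  base <- MutationSet("p.Ala65Val", 65L, "A", "V", 1L,
                      phenotypes = list("renal_disease"))
  more <- rbindMs(base, MutationSet("p.Ala105Val", 105L, "A", "V", 1L,
                                    phenotypes = list("renal_disease")))
  m1 <- impairmentCells(buildImpairmentMatrix(base, interactorFixture()))
  m2 <- impairmentCells(buildImpairmentMatrix(more, interactorFixture()))
  expect_true(all(m2[m1 == "affected"] == "affected"))
})

test_that("the impairment matrix is bit-reproducible and round-trips to TSV", {
  ms <- syntheticCuratedTable()
  ints <- syntheticInteractors()
  im1 <- buildImpairmentMatrix(ms, ints)
  im2 <- buildImpairmentMatrix(ms, ints)
  expect_identical(impairmentCells(im1), impairmentCells(im2))
  p <- tempfile(fileext = ".tsv")
  writeImpairmentMatrix(im1, p)
  back <- utils::read.delim(p, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(back), nrow(impairmentCells(im1)))
})

test_that("PTM overlap reports only sites with missense mutations", {
  sites <- data.frame(position = c(68L, 43L), type = "phosphorylation",
                      enzyme = c("GSK3B", "CSNK2A1"), stringsAsFactors = FALSE)
  ms <- MutationSet(c("p.Ser68Trp", "p.Ser68="), c(68L, 68L), "S",
                    c("W", "="), c(2L, 1L),
                    phenotypes = list("renal_disease", "renal_disease"))
  ov <- ptmOverlap(ms, sites)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$position, 68L)
  expect_equal(ov$variants, "p.Ser68Trp")  # synonymous excluded
  expect_equal(ov$phenotypes, "renal_disease")
  # no overlap at all
  ms2 <- MutationSet("p.Ala5Val", 5L, "A", "V", 1L)
  expect_equal(nrow(ptmOverlap(ms2, sites)), 0L)
  # report size bounded by the number of sites
  expect_lte(nrow(ptmOverlap(syntheticCuratedTable(), syntheticPTMSites())),
             nrow(syntheticPTMSites()))
})

test_that("PTM table validation enforces bounds and enzyme presence", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("position\ttype\tenzyme", "999\tphosphorylation\tGSK3B"), p)
  expect_error(readPTMTable(p), class = "vhlG2P_input_error")
  writeLines(c("position\ttype\tenzyme", "68\tphosphorylation\t "), p)
  expect_error(readPTMTable(p), class = "vhlG2P_input_error")
  writeLines(c("position\ttype\tenzyme", "68\tglycation\tX"), p)
  expect_error(readPTMTable(p), class = "vhlG2P_input_error")
})
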