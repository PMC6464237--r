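test_that("HGVS protein labels parse into wt/position/mut", {
  h <- parseHGVS(c("p.Arg167Trp", "p.Asn78Ser", "p.Arg200=", "garbage",
                   "p.Xyz12Trp"))
  expect_equal(h$wt_aa[1:3], c("R", "N", "R"))
  expect_equal(h$position[1:3], c(167L, 78L, 200L))
  expect_equal(h$mut_aa[1:3], c("W", "S", "="))
  expect_true(h$synonymous[3])
  expect_true(all(is.na(h$position[4:5])))
})

test_that("phenotype normalization collapses renal manifestations and folds case", {
  n <- normalizePhenotype(c("ccRCC", "Renal cysts", "RCC", "renal carcinoma",
                            "PHEOCHROMOCYTOMA", "made-up label"))
  expect_equal(unname(n[1:4]), rep("renal_disease", 4))
  expect_equal(unname(n[5]), "pheochromocytoma")
  expect_equal(unname(n[6]), "other")
  expect_equal(attr(n, "unmapped"), "made-up label")
  # idempotence: normalizing a normalized term is a fixed point
  again <- normalizePhenotype(unname(n))
  expect_equal(as.character(again), as.character(n))
})

test_that("reading a mutation table parses rows and reports malformed HGVS", {
  p <- writeTinyTSV(c(
    "p.Arg167Trp\t200\tccRCC;pheochromocytoma\ts1",
    "p.Tyr98His\t20\tretinal hemangioblastoma\ts2",
    "p.BadToken\t1\tccRCC\ts3",
    "p.Ser65Leu\t5\trenal cysts\ts4",
    "p.Arg200=\t2\tpolycythemia\ts5"))
  ms <- readMutationTable(p)
  expect_equal(length(ms), 4L)
  err <- attr(ms, "errors")
  expect_equal(nrow(err), 1L)
  expect_equal(err$variant, "p.BadToken")
  v <- mutationTable(ms)
  expect_equal(v$position, c(167L, 98L, 65L, 200L))
  expect_true(v$synonymous[4])
  expect_equal(mutationPhenotypes(ms)[[1]],
               c("pheochromocytoma", "renal_disease"))
})

test_that("header-only file yields an empty set; missing column errors", {
  p <- writeTinyTSV(character())
  ms <- readMutationTable(p)
  expect_equal(length(ms), 0L)
  bad <- tempfile(fileext = ".tsv")
  writeLines("variant\tcount", bad)
  expect_error(readMutationTable(bad), class = "vhlG2P_config_error")
})

test_that("mutation tables round-trip through write/read field-identically", {
  ms <- tinyMutations()
  p <- tempfile(fileext = ".tsv")
  writeMutationTable(ms, p)
  back <- readMutationTable(p)
  expect_equal(mutationTable(back)[, c("variant", "position", "wt_aa",
                                       "mut_aa", "n_patients")],
               mutationTable(ms)[, c("variant", "position", "wt_aa",
                                     "mut_aa", "n_patients")])
  expect_equal(mutationPhenotypes(back),
               lapply(mutationPhenotypes(ms), sort))
})

test_that("single-phenotype filter uses cardinality after normalization", {
  p <- writeTinyTSV(c(
    "p.Arg167Trp\t5\tccRCC;pheochromocytoma\ts1",   # truly multi
    "p.Ser65Leu\t1\tccRCC;renal cysts\ts2",         # collapses to renal only
    "p.Tyr98His\t1\tretinal hemangioblastoma\ts3")) # single
  ms <- readMutationTable(p)
  single <- filterSinglePhenotype(ms)
  expect_equal(mutationTable(single)$variant, c("p.Ser65Leu", "p.Tyr98His"))
  # subset + idempotence
  expect_equal(length(filterSinglePhenotype(single)), length(single))
  expect_true(all(mutationTable(single)$variant %in% mutationTable(ms)$variant))
})

test_that("MutationSet validity rejects inconsistent records", {
  expect_error(MutationSet("p.Arg1Arg", 1L, "R", "R", 1L),
               "identical")
  expect_error(MutationSet("p.Arg0Trp", 0L, "R", "W", 1L), ">= 1")
  expect_error(new("MutationSet", variants = mutationTable(tinyMutations()),
                   phenotypes = list(), log = character()), "parallel")
})

test_that("PDB structures load the requested chain without waters", {
  p <- tempfile(fileext = ".pdb")
  generateToyStructure("helix", path = p)
  st <- readStructure(p)
  res <- structureResidues(st)
  expect_equal(nrow(res), 12L)
  a <- structureAtoms(st)
  expect_equal(sum(a$elety == "CA"), 12L)
  expect_error(readStructure(p, chain = "Z"), class = "vhlG2P_input_error")
  # two-chain file: only the requested chain is kept
  a2 <- a; a2$chain <- "H"; a2$resno <- a2$resno + 100L
  both <- rbind(a, a2)
  p2 <- tempfile(fileext = ".pdb")
  vhlG2P:::.writePDB(both, p2)
  stH <- readStructure(p2, chain = "H")
  expect_true(all(structureAtoms(stH)$chain == "H"))
  expect_equal(nrow(structureResidues(stH)), 12L)
})

test_that("surface config ships the printed interface sizes", {
  surf <- defaultSurfaces()
  expect_equal(surfaceSizes(surf)[c("A", "B", "C", "D", "E")],
               c(A = 35L, B = 43L, C = 49L, D = 59L, E = 23L))
  # round-trip through a user JSON config
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(list(A = "1-3", B = c("5", "7-8")), p,
                       auto_unbox = TRUE)
  s2 <- readSurfaceConfig(p)
  expect_equal(surfaceResidues(s2, "A"), 1:3)
  expect_equal(surfaceResidues(s2, "B"), c(5L, 7L, 8L))
})
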