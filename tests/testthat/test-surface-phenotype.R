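test_that("named pVHL residues map to their narrative surfaces", {
  surf <- defaultSurfaces()
  expect_equal(assignSurface(167, surf), "A")
  expect_equal(assignSurface(98, surf), "B")
  expect_equal(assignSurface(149, surf), "C")
  expect_equal(assignSurface(33, surf), "D")
  expect_equal(assignSurface(200, surf), "E")
  expect_equal(assignSurface(61, surf), character())  # between D and B
})

test_that("mutated fraction counts distinct positions and rounds to integer percent", {
  surf <- SurfaceSet(list(S = 1:10))
  ms <- MutationSet(variant = sprintf("p.Ala%dVal", c(2, 5, 9, 5)),
                    position = c(2L, 5L, 9L, 5L), wt_aa = "A", mut_aa = "V",
                    n_patients = rep(1L, 4))
  st <- mutatedFraction(ms, surf, "S")
  expect_equal(st$n_mutated_positions, 3L)
  expect_equal(st$mutated_fraction_pct, 30)
  # duplication invariance
  expect_equal(mutatedFraction(rbindMs(ms, ms), surf, "S")$mutated_fraction_pct, 30)
  # empty surface hit
  ms0 <- MutationSet("p.Ala99Val", 99L, "A", "V", 1L)
  expect_equal(mutatedFraction(ms0, surf, "S")$mutated_fraction_pct, 0)
})

test_that("phenotype distributions report one-decimal proportions summing to 100", {
  ms <- MutationSet("p.Ala5Val", 5L, "A", "V", 1L,
                    phenotypes = list("renal_disease"))
  d <- phenotypeDistribution(ms, id = "overall")
  expect_equal(unname(phenotypeProportions(d)), 100)
  # the 27-record C-terminal-style profile: 11/5/4/4/2/1
  counts <- c(renal_disease = 11L, pheochromocytoma = 5L, polycythemia = 4L,
              colorectal_cancer = 4L, glial_tumor = 2L, other = 1L)
  terms <- rep(names(counts), counts)
  ms27 <- MutationSet(variant = sprintf("p.Ala%dVal", 200 + seq_along(terms) %% 14),
                      position = 200L + seq_along(terms) %% 14L,
                      wt_aa = "A", mut_aa = "V",
                      n_patients = rep(1L, length(terms)),
                      phenotypes = as.list(terms))
  d27 <- phenotypeDistribution(ms27, id = "overall")
  expect_equal(nRecords(d27), 27L)
  p <- phenotypeProportions(d27)
  expect_equal(unname(p[c("renal_disease", "pheochromocytoma", "polycythemia",
                          "colorectal_cancer", "glial_tumor", "other")]),
               c(40.7, 18.5, 14.8, 14.8, 7.4, 3.7))
  expect_lt(abs(sum(p) - 100), 0.1 * length(p))
})

test_that("proportions sum to 100 within rounding over generated sets", {
  for (s in 1:5) {
    ms <- generateMutationTable(synthConfig(n_variants = 200, seed = s))
    d <- phenotypeDistribution(filterSinglePhenotype(ms), id = "overall")
    if (nRecords(d) > 0)
      expect_lt(abs(sum(phenotypeProportions(d)) - 100),
                0.05 * length(d@counts) + 1e-9)
  }
})

test_that("zero records on a surface give an empty distribution, not an error", {
  ms <- MutationSet("p.Ala5Val", 5L, "A", "V", 1L,
                    phenotypes = list("renal_disease"))
  d <- phenotypeDistribution(ms, defaultSurfaces(), "E")
  expect_equal(nRecords(d), 0L)
  expect_length(phenotypeProportions(d), 0L)
})

test_that("identical groups give statistic 0 and p-value 1", {
  d1 <- new("PhenotypeDistribution", surfaceId = "A",
            counts = c(renal_disease = 5L, pheochromocytoma = 5L),
            nRecords = 10L)
  d2 <- new("PhenotypeDistribution", surfaceId = "B",
            counts = c(renal_disease = 5L, pheochromocytoma = 5L),
            nRecords = 10L)
  for (m in c("chi_square", "permutation")) {
    r <- compareSurfaces(list(d1, d2), m, nPermutations = 200, seed = 1)
    expect_equal(r$statistic, 0)
    expect_equal(r$p_value, 1)
  }
})

test_that("chi-square statistic and p-value match stats::chisq.test", {
  d1 <- new("PhenotypeDistribution", surfaceId = "A",
            counts = c(renal_disease = 12L, pheochromocytoma = 3L,
                       polycythemia = 5L), nRecords = 20L)
  d2 <- new("PhenotypeDistribution", surfaceId = "B",
            counts = c(renal_disease = 6L, pheochromocytoma = 10L,
                       polycythemia = 4L), nRecords = 20L)
  r <- compareSurfaces(list(d1, d2), "chi_square")
  tab <- rbind(c(12, 3, 5), c(6, 10, 4))
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, unname(ref$p.value))
})

test_that("permutation p-values are seeded-reproducible and near the MC chi-square", {
  d1 <- new("PhenotypeDistribution", surfaceId = "A",
            counts = c(renal_disease = 12L, pheochromocytoma = 6L),
            nRecords = 18L)
  d2 <- new("PhenotypeDistribution", surfaceId = "B",
            counts = c(renal_disease = 6L, pheochromocytoma = 12L),
            nRecords = 18L)
  r1 <- compareSurfaces(list(d1, d2), "permutation", nPermutations = 2000,
                        seed = 11)
  r2 <- compareSurfaces(list(d1, d2), "permutation", nPermutations = 2000,
                        seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  # independent Monte-Carlo oracle from stats::chisq.test
  ref <- suppressWarnings(stats::chisq.test(rbind(c(12, 6), c(6, 12)),
                                            simulate.p.value = TRUE, B = 10000))
  mcSd <- sqrt(ref$p.value * (1 - ref$p.value) / 2000)
  expect_lt(abs(r1$p_value - ref$p.value), 4 * mcSd + 0.01)
})

test_that("the ANOVA route tests per-position counts grouped by surface", {
  ms <- generateMutationTable(synthConfig(n_variants = 400, seed = 9))
  r <- compareSurfaces(method = "anova", x = ms)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_equal(r$method, "anova")
})

test_that("degenerate comparisons raise input errors", {
  d1 <- new("PhenotypeDistribution", surfaceId = "A",
            counts = c(renal_disease = 5L), nRecords = 5L)
  d0 <- new("PhenotypeDistribution", surfaceId = "B",
            counts = integer(), nRecords = 0L)
  expect_error(compareSurfaces(list(d1, d0), "chi_square"),
               class = "vhlG2P_input_error")
})
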