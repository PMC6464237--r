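test_that("net specs validate bipartiteness and arc endpoints", {
  # 1 place, 1 transition, self-loop: valid
  net <- buildNet(list(
    places = data.frame(id = "p1", label = "p", initial = 1L),
    transitions = data.frame(id = "t1", label = "t"),
    arcs = data.frame(from = c("p1", "t1"), to = c("t1", "p1"),
                      weight = 1L)))
  expect_s4_class(net, "PetriNet")
  # place-to-place arc rejected
  expect_error(buildNet(list(
    places = data.frame(id = c("p1", "p2"), label = "p", initial = 0L),
    transitions = data.frame(id = "t1", label = "t"),
    arcs = data.frame(from = "p1", to = "p2", weight = 1L))),
    class = "vhlG2P_validation_error")
  # dangling endpoint rejected with the offender named
  expect_error(buildNet(list(
    places = data.frame(id = "p1", label = "p", initial = 0L),
    transitions = data.frame(id = "t1", label = "t"),
    arcs = data.frame(from = "p1", to = "tX", weight = 1L))),
    "tX")
})

test_that("the hypoxia fixture net builds with 9 places and 8 transitions", {
  net <- buildNet(fixturePetriNet())
  expect_equal(nrow(net@places), 9L)
  expect_equal(nrow(net@transitions), 8L)
  expect_true(all(c("p_54", "p_38", "p_39", "p_60") %in% net@places$id))
  expect_true(all(c("t_181", "t_109") %in% net@transitions$id))
})

test_that("enabled transitions agree with a brute-force oracle on random nets", {
  for (s in 1:40) {
    net <- randomNet(s)
    m <- initialMarking(net)
    expect_setequal(enabledTransitions(net, m), oracleEnabled(net, m))
    # also after a knockout
    k <- knockout(net, net@transitions$id[1])
    expect_setequal(enabledTransitions(k, m), oracleEnabled(k, m))
  }
})

test_that("empty markings enable only source transitions; weights gate enabling", {
  net <- buildNet(list(
    places = data.frame(id = "p1", label = "p", initial = 1L),
    transitions = data.frame(id = c("t_src", "t_need2"), label = "t"),
    arcs = data.frame(from = c("t_src", "p1"), to = c("p1", "t_need2"),
                      weight = c(1L, 2L))))
  m0 <- c(p1 = 0L)
  expect_equal(enabledTransitions(net, m0), "t_src")
  expect_equal(enabledTransitions(net, c(p1 = 1L)), "t_src")
  expect_setequal(enabledTransitions(net, c(p1 = 2L)), c("t_src", "t_need2"))
})

test_that("firing moves tokens by arc weights and rejects bad firings", {
  net <- buildNet(list(
    places = data.frame(id = c("p", "q"), label = c("p", "q"),
                        initial = c(3L, 0L)),
    transitions = data.frame(id = "t", label = "t"),
    arcs = data.frame(from = c("p", "t"), to = c("t", "q"),
                      weight = c(2L, 1L))))
  m1 <- fireTransition(net, initialMarking(net), "t")
  expect_equal(m1, c(p = 1L, q = 1L))
  expect_error(fireTransition(net, c(p = 1L, q = 0L), "t"),
               class = "vhlG2P_state_error")
  expect_error(fireTransition(knockout(net, "t"), initialMarking(net), "t"),
               class = "vhlG2P_state_error")
  # self-loop conservation
  loop <- buildNet(list(
    places = data.frame(id = "p", label = "p", initial = 1L),
    transitions = data.frame(id = "t", label = "t"),
    arcs = data.frame(from = c("p", "t"), to = c("t", "p"), weight = 1L)))
  expect_equal(fireTransition(loop, c(p = 1L), "t"), c(p = 1L))
})

test_that("a net with no enabled transition holds its marking (deadlock)", {
  net <- buildNet(list(
    places = data.frame(id = "p", label = "p", initial = 0L),
    transitions = data.frame(id = "t", label = "t"),
    arcs = data.frame(from = c("p", "t"), to = c("t", "p"), weight = 1L)))
  res <- simulateNet(net, steps = 50, replicates = 2, seed = 1)
  expect_equal(experimentSummary(res)$mean, 0)
  expect_equal(res@config$mean_deadlocks, 50)
})

test_that("a lone source transition accumulates one token per step", {
  net <- buildNet(list(
    places = data.frame(id = "q", label = "q", initial = 0L),
    transitions = data.frame(id = "t", label = "t"),
    arcs = data.frame(from = "t", to = "q", weight = 1L)))
  res <- simulateNet(net, steps = 100, replicates = 1, seed = 1)
  expect_equal(experimentSummary(res)$mean, 100)
})

test_that("simulations are bit-identical given the same seed", {
  net <- buildNet(fixturePetriNet())
  r1 <- simulateNet(net, steps = 300, replicates = 5, seed = 42)
  r2 <- simulateNet(net, steps = 300, replicates = 5, seed = 42)
  expect_identical(experimentSummary(r1), experimentSummary(r2))
  expect_identical(r1@trajectories, r2@trajectories)
  r3 <- simulateNet(net, steps = 300, replicates = 5, seed = 43)
  expect_false(identical(experimentSummary(r1), experimentSummary(r3)))
})

test_that("no reachable marking goes negative and knockouts never fire", {
  for (s in 1:60) {
    net <- randomNet(s)
    ko <- knockout(net, sample(net@transitions$id, 1))
    res <- simulateNet(ko, steps = 40, replicates = 1, seed = s)
    expect_true(all(experimentSummary(res)$mean >= 0))
    expect_true(all(res@trajectories >= 0))
    f <- experimentFirings(res)
    expect_equal(f$mean_count[f$transition %in% ko@disabled], 0)
  }
})

test_that("unit-weight cycles conserve their token total under any policy", {
  cyc <- buildNet(list(
    places = data.frame(id = c("a", "b"), label = c("a", "b"),
                        initial = c(3L, 1L)),
    transitions = data.frame(id = c("t1", "t2"), label = c("t1", "t2")),
    arcs = data.frame(from = c("a", "t1", "b", "t2"),
                      to = c("t1", "b", "t2", "a"), weight = 1L)))
  for (pol in c("random_single_fire", "maximal_step")) {
    res <- simulateNet(cyc, steps = 200, replicates = 3, seed = 5,
                       policy = pol)
    expect_equal(sum(experimentSummary(res)$mean), 4)
  }
})

test_that("marking perturbations add pointwise and validate place ids", {
  m <- c(p_54 = 2L, p_38 = 0L)
  expect_equal(perturbMarking(m, c(p_54 = 5L)), c(p_54 = 7L, p_38 = 0L))
  expect_equal(perturbMarking(m, integer()), m)
  expect_error(perturbMarking(m, c(nope = 1L)), class = "vhlG2P_input_error")
  # combined AKT-branch perturbation on the fixture
  net <- buildNet(fixturePetriNet())
  m0 <- perturbMarking(initialMarking(net),
                       c(p_38 = 4L, p_39 = 4L, p_60 = 4L))
  expect_equal(unname(m0[c("p_38", "p_39", "p_60")]), rep(4L, 3))
})

test_that("experiment comparison reports deltas and pseudocount log ratios", {
  net <- buildNet(fixturePetriNet())
  wt <- simulateNet(net, steps = 200, replicates = 3, seed = 2)
  expect_equal(compareExperiments(wt, wt)$delta, rep(0, 9))
  # pseudocount arithmetic: wt 0, perturbed 7 -> log2(8/1) = 3
  a <- wt; b <- wt
  a@summary$mean <- rep(0, 9); b@summary$mean <- rep(7, 9)
  expect_equal(compareExperiments(a, b)$log2_ratio, rep(3, 9))
  mismatch <- wt
  mismatch@summary <- wt@summary[-1, ]
  expect_error(compareExperiments(wt, mismatch), class = "vhlG2P_input_error")
})

test_that("knocking out HIF degradation raises HIF and VEGF over wild-type", {
  net <- buildNet(fixturePetriNet())
  wt <- simulateNet(net, steps = 1000, replicates = 10, seed = 7)
  ko <- simulateNet(knockout(net, "t_181"), steps = 1000, replicates = 10,
                    seed = 7)
  cmp <- compareExperiments(wt, ko)
  expect_gt(cmp$delta[cmp$place == "HIF"], 0)
  expect_gt(cmp$delta[cmp$place == "VEGF"], 0)
})

test_that("PNML subset round-trips through the reader", {
  pnml <- tempfile(fileext = ".pnml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pnml><net id="n1">',
    '<place id="p1"><name><text>HIF</text></name>',
    '<initialMarking><text>2</text></initialMarking></place>',
    '<transition id="t1"><name><text>deg</text></name></transition>',
    '<arc id="a1" source="p1" target="t1">',
    '<inscription><text>2</text></inscription></arc>',
    '</net></pnml>'), pnml)
  net <- readPNML(pnml)
  expect_equal(net@places$id, "p1")
  expect_equal(initialMarking(net), c(p1 = 2L))
  expect_equal(net@arcs$weight, 2L)
  expect_equal(net@transitions$label, "deg")
})
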