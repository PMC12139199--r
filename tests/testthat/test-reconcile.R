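test_that("LCA mapping returns leaves, internal MRCAs and the root", {
  st <- ape::read.tree(text = "(((indica1,indica2),(japonica1,japonica2)),out);")
  expect_equal(speciesNodeLabel(lcaMap("indica1", st), st), "indica1")
  allTaxa <- c("indica1", "indica2", "japonica1", "japonica2", "out")
  expect_equal(lcaMap(allTaxa, st), length(st$tip.label) + 1L)
  # brute-force check of the mixed-subspecies clade
  sets <- oracleSpeciesSets(st)
  got <- lcaMap(c("indica1", "japonica1"), st)
  expect_equal(got, oracleMapNode(c("indica1", "japonica1"), sets))
  expect_lt(length(sets[[got]]), length(st$tip.label))  # not the root
  expect_error(lcaMap("martian", st), "martian")
})

test_that("a misrooted congruent gene tree recovers the species rooting", {
  st <- fourTaxonSpeciesTree()
  # same topology, rooted wrongly (D inside)
  gt <- readTree("((D|g4,C|g3),(A|g1,B|g2));")
  r <- rootGeneTree(gt, st)
  expect_equal(attr(r, "score"), 0)
  expect_equal(attr(r, "dups"), 0)
})

test_that("a tree of two species-tree copies roots between the copies", {
  st <- fourTaxonSpeciesTree()
  gt <- readTree(paste0("((((A|g1,B|g2),C|g3),D|g4),",
                        "(((A|g5,B|g6),C|g7),D|g8));"))
  r <- rootGeneTree(gt, st)
  expect_equal(attr(r, "dups"), 1)
  expect_equal(attr(r, "losses"), 0)
  ev <- detectDuplications(r, st)
  expect_equal(nrow(gdEvents(ev)), 1L)
  expect_equal(gdEvents(ev)$species_node, lcaMap(c("A", "B", "C", "D"), st))
})

test_that("rooting score equals the exhaustive all-branch minimum", {
  st <- fourTaxonSpeciesTree()
  set.seed(101)
  for (i in 1:100) {
    nwk <- randomGeneTreeNewick(7, c("A", "B", "C", "D"))
    gt <- readTree(nwk)
    r <- rootGeneTree(gt, st)
    orc <- oracleMinRootScore(ape::read.tree(text = nwk), st)
    expect_equal(attr(r, "score"), orc$score)
  }
})

test_that("duplication calls obey the shared-species and support rules", {
  stAB <- ape::read.tree(text = "(A,B);")
  # single-copy congruent tree: no duplication
  expect_equal(nrow(gdEvents(detectDuplications(
    readTree("(A|g1,B|g2);"), stAB))), 0L)
  # textbook duplication with full support
  ev <- detectDuplications(
    readTree("((A|g1,B|g2)100,(A|g3,B|g4)100)100;"), stAB)
  expect_equal(nrow(gdEvents(ev)), 1L)
  expect_equal(gdEvents(ev)$species_label, "MRCA(A,B)")
  # node support below bp: rejected
  expect_equal(nrow(gdEvents(detectDuplications(
    readTree("((A|g1,B|g2)100,(A|g3,B|g4)100)60;"), stAB))), 0L)
  # child support below sub_bp: rejected
  expect_equal(nrow(gdEvents(detectDuplications(
    readTree("((A|g1,B|g2)50,(A|g3,B|g4)100)100;"), stAB))), 0L)
  # missing supports pass
  expect_equal(nrow(gdEvents(detectDuplications(
    readTree("((A|g1,B|g2),(A|g3,B|g4));"), stAB))), 1L)
})

test_that("min_shared_species counts taxa shared by both copies", {
  st <- ape::read.tree(text = "((A,B),C);")
  # copies {A,B} and {A,C} share only A -> rejected at minShared 2
  ev <- detectDuplications(
    readTree("((A|g1,B|g2)100,(A|g3,C|g4)100)100;"), st)
  expect_equal(nrow(gdEvents(ev)), 0L)
  ev1 <- detectDuplications(
    readTree("((A|g1,B|g2)100,(A|g3,C|g4)100)100;"), st, minShared = 1)
  expect_equal(nrow(gdEvents(ev1)), 1L)
})

test_that("raising bp or minShared never increases detected events", {
  st <- fourTaxonSpeciesTree()
  set.seed(77)
  for (i in 1:30) {
    nwk <- randomGeneTreeNewick(8, c("A", "B", "C", "D"))
    gt0 <- readTree(nwk)
    # attach random supports
    gt <- gt0
    gt$support[(gt$nTip + 1):gt$nNode] <-
      sample(c(NA, 40, 60, 80, 100), gt$nNode - gt$nTip, replace = TRUE)
    r <- rootGeneTree(gt, st)
    n70 <- nrow(gdEvents(detectDuplications(r, st, bp = 70, subBp = 70)))
    n90 <- nrow(gdEvents(detectDuplications(r, st, bp = 90, subBp = 90)))
    n50 <- nrow(gdEvents(detectDuplications(r, st, bp = 50, subBp = 50)))
    expect_lte(n90, n70)
    expect_lte(n70, n50)
    s2 <- nrow(gdEvents(detectDuplications(r, st, minShared = 2)))
    s3 <- nrow(gdEvents(detectDuplications(r, st, minShared = 3)))
    expect_lte(s3, s2)
  }
})

test_that("implementation matches the brute-force oracle on random trees", {
  st <- fourTaxonSpeciesTree()
  set.seed(55)
  for (i in 1:60) {
    nwk <- randomGeneTreeNewick(sample(4:7, 1), c("A", "B", "C", "D"))
    gt <- readTree(nwk)
    r <- rootGeneTree(gt, st)
    orc <- oracleMinRootScore(ape::read.tree(text = nwk), st)
    expect_equal(attr(r, "score"), orc$score)
    # detection on the chosen rooting agrees with the independent walker
    mine <- sort(gdEvents(detectDuplications(r, st))$species_node)
    rphy <- ape::read.tree(text = writeTree(r))
    expect_equal(mine, sort(oracleDetect(rphy, st)))
  }
})

test_that("event summaries count once per event and sum to the total", {
  st <- riceSpeciesTree()
  focal <- riceFocalNode(st)
  sim <- simulateGeneTrees(st, 12,
    list(list(node = focal, count = 5, class = "ABAB"),
         list(node = lcaMap(c("ind1", "ind2"), st), count = 3,
              class = "ABAB")), seed = 21)
  ev <- detectDuplicationsSet(sim$trees, st)
  smry <- summarizeGD(ev)
  expect_equal(sum(smry$n_events), nrow(gdEvents(ev)))
  expect_equal(smry$n_events[smry$species_node == focal], 5L)
  expect_equal(
    smry$n_events[smry$species_node == lcaMap(c("ind1", "ind2"), st)], 3L)
  # empty input: all zeros
  sim0 <- simulateGeneTrees(st, 3, list(), seed = 1)
  ev0 <- detectDuplicationsSet(sim0$trees, st)
  expect_true(all(summarizeGD(ev0)$n_events == 0L))
})
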