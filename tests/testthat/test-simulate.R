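test_that("largest-remainder allocation is exact and deterministic", {
  expect_equal(largestRemainder(100, c(0.4, 0.3, 0.2, 0.1)),
               c(40L, 30L, 20L, 10L))
  expect_equal(sum(largestRemainder(7, c(1, 1, 1) / 3)), 7L)
  expect_equal(largestRemainder(10000, c(0.9646, 0.0289, 0.0065)),
               c(9646L, 289L, 65L))
  expect_error(largestRemainder(10, c(0.5, 0.4)), "sum to 1")
  expect_error(largestRemainder(10, c(1.2, -0.2)), "nonnegative")
})

test_that("identical parameters and seed give byte-identical outputs", {
  st <- riceSpeciesTree()
  spec <- list(list(node = c("ind1", "jap1"), count = 3, class = "ABAB"))
  a <- simulateGeneTrees(st, 6, spec, lossProb = 0.3, seed = 9)
  b <- simulateGeneTrees(st, 6, spec, lossProb = 0.3, seed = 9)
  expect_identical(a$newick, b$newick)
  expect_identical(a$truth, b$truth)

  p1 <- file.path(tempdir(), "d1.vcf"); p2 <- file.path(tempdir(), "d2.vcf")
  simulateTrio(50, c(0.4, 0.3, 0.2, 0.1), seed = 5, vcfPath = p1)
  simulateTrio(50, c(0.4, 0.3, 0.2, 0.1), seed = 5, vcfPath = p2)
  expect_identical(readLines(p1), readLines(p2))

  e1 <- simulateExpression(30, c(A = 0.5, POD = 0.5), seed = 4)
  e2 <- simulateExpression(30, c(A = 0.5, POD = 0.5), seed = 4)
  expect_identical(e1$tpm, e2$tpm)

  c1 <- simulateCodonPair(100, 5, 3, seed = 8)
  c2 <- simulateCodonPair(100, 5, 3, seed = 8)
  expect_identical(c1, c2)
})

test_that("planted duplications reconcile to the planted node and class", {
  st <- riceSpeciesTree()
  focal <- riceFocalNode(st)
  for (cls in c("ABAB", "ABAX", "ABXB")) {
    sim <- simulateGeneTrees(st, 4,
      list(list(node = focal, count = 4, class = cls)), seed = 2)
    ev <- detectDuplicationsSet(sim$trees, st)
    expect_equal(nrow(gdEvents(ev)), 4L)
    expect_true(all(gdEvents(ev)$species_node == focal))
    topo <- classifyTopologySet(ev, focal)
    expect_true(all(topo$topology == cls))
  }
})

test_that("with no planted events gene trees are congruent: zero GDs", {
  st <- riceSpeciesTree()
  sim <- simulateGeneTrees(st, 10, list(), seed = 3)
  ev <- detectDuplicationsSet(sim$trees, st)
  expect_equal(nrow(gdEvents(ev)), 0L)
})

test_that("unrealizable duplication placement errors", {
  st <- riceSpeciesTree()
  expect_error(simulateGeneTrees(st, 2,
    list(list(node = "ind1", count = 1, class = "ABAB")), seed = 1),
    "terminal")
})

test_that("loss-affected truth enumerates survivors reproducibly", {
  st <- riceSpeciesTree()
  focal <- riceFocalNode(st)
  sim <- simulateGeneTrees(st, 50,
    list(list(node = focal, count = 50, class = "ABAB")),
    lossProb = 0.25, seed = 13)
  # survivors recorded in truth must be exactly the leaves of the trees
  for (i in seq_len(10)) {
    gt <- sim$trees[[sim$truth$family[i]]]
    copies <- c(strsplit(sim$truth$survL[i], ",")[[1]],
                strsplit(sim$truth$survR[i], ",")[[1]])
    expect_true(all(copies %in% gt$taxon[seq_len(gt$nTip)]))
  }
  # detector calls equal the truth's detectable events
  ev <- detectDuplicationsSet(sim$trees, st)
  calls <- gdEvents(ev)
  truthDet <- sim$truth[sim$truth$detectable, ]
  expect_setequal(calls$family, truthDet$family)
})

test_that("codon pairs plant exact substitution counts without stops", {
  cp <- simulateCodonPair(100, 0, 0, seed = 1)
  expect_identical(cp$seq1, cp$seq2)
  cp <- simulateCodonPair(100, 5, 0, seed = 2)
  expect_equal(nchar(cp$seq1), 300L)
  r <- ng86Pair(cp$seq1, cp$seq2)
  expect_equal(r@Sd, 5)
  expect_equal(r@Nd, 0)
  expect_equal(r@nCodons, 100L)   # no codon became a stop
  expect_error(simulateCodonPair(50, 200, 0), "insufficient")
})

test_that("trio class counts are the exact largest-remainder allocation", {
  sim <- simulateTrio(100, c(0.4, 0.3, 0.2, 0.1), seed = 6)
  expect_equal(unname(table(sim$sites$true_class)[
    c("inherited_P1", "inherited_P2", "shared", "de_novo")]),
    c(40L, 30L, 20L, 10L), ignore_attr = TRUE)
  one <- simulateTrio(25, c(1, 0, 0, 0), seed = 1)
  tc <- classifyTrio(one$sites)
  expect_true(all(trioSites(tc)$class == "inherited_P1"))
  expect_error(simulateTrio(0, c(1, 0, 0, 0)), "positive")
})

test_that("expression generator places F1 means by mode", {
  # noise-free additive: F1 mean is exactly the mid-parent
  se <- simulateExpression(10, c(A = 1), fold = 2, nReps = 3, cv = 0)
  mp <- (rowMeans(se$tpm[, se$p1Cols]) + rowMeans(se$tpm[, se$p2Cols])) / 2
  expect_equal(rowMeans(se$tpm[, se$f1Cols]), mp)
  expect_error(simulateExpression(10, c(A = 1), nReps = 1), "nReps")
  expect_error(simulateExpression(10, c(A = 0.5, POD = 0.2)), "sum to 1")
})

test_that("planted POD genes are recovered at high rate", {
  se <- simulateExpression(50, c(POD = 1), fold = 4, nReps = 6,
                           cv = 0.1, seed = 1)
  hm <- classifyExpressionModes(se$tpm, se$p1Cols, se$p2Cols, se$f1Cols)
  expect_gte(mean(modeCalls(hm)$mode == "POD"), 0.9)
})

test_that("noise-free classification reproduces planted truth exactly", {
  mix <- c(A = 1, PD = 1, ND = 1, PPD = 1, NPD = 1, POD = 1, NOD = 1) / 7
  se <- simulateExpression(70, mix, fold = 4, nReps = 4, cv = 0, seed = 2)
  hm <- classifyExpressionModes(se$tpm, se$p1Cols, se$p2Cols, se$f1Cols)
  expect_identical(modeCalls(hm)$mode, se$truth$mode)
})
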