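test_that("Newick parsing extracts leaves, taxa and supports", {
  gt <- readTree("((A|g1,B|g2)95,C|g3);")
  expect_equal(gt$nTip, 3L)
  expect_setequal(gt$taxon[1:3], c("A", "B", "C"))
  expect_setequal(gt$gene[1:3], c("g1", "g2", "g3"))
  sup <- gt$support[!is.na(gt$support)]
  expect_equal(sup, 95)
})

test_that("missing supports are recorded as missing, not zero", {
  gt <- readTree("((A|g1,B|g2),C|g3);")
  expect_true(all(is.na(gt$support)))
})

test_that("supports in [0,1] are rescaled to 0-100 with a warning", {
  expect_warning(gt <- readTree("((A|g1,B|g2)0.95,C|g3);"),
                 "rescaled")
  expect_equal(gt$support[!is.na(gt$support)], 95)
})

test_that("malformed Newick and unparseable leaf labels raise errors", {
  expect_error(readTree("((A|g1,B|g2"), "parse")
  expect_error(readTree("((A_g1,Bg2),C|g3);", delim = "|"),
               "does not parse")
})

test_that("Newick round-trip is lossless on random simulated trees", {
  set.seed(42)
  taxa <- c("A", "B", "C", "D", "E")
  for (i in 1:60) {
    nwk <- randomGeneTreeNewick(sample(3:9, 1), taxa)
    gt <- readTree(nwk)
    out1 <- writeTree(gt)
    gt2 <- readTree(out1)
    out2 <- writeTree(gt2)
    expect_identical(out1, out2)
    expect_setequal(gt$label[seq_len(gt$nTip)], gt2$label[seq_len(gt2$nTip)])
    # topology preserved: identical split sets
    p1 <- ape::read.tree(text = out1)
    p2 <- ape::read.tree(text = nwk)
    expect_equal(ape::dist.topo(ape::unroot(p1), ape::unroot(p2)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("round-trip preserves branch lengths and supports", {
  nwk <- "((A|g1:0.1,B|g2:0.2)88:0.05,C|g3:0.3);"
  gt <- readTree(nwk)
  gt2 <- readTree(writeTree(gt))
  expect_equal(sort(gt2$length[!is.na(gt2$length)]),
               c(0.05, 0.1, 0.2, 0.3))
  expect_equal(gt2$support[!is.na(gt2$support)], 88)
})

test_that("gene order ordinals rank genes by start within chromosome", {
  df <- data.frame(gene_id = c("g3", "g1", "g2"),
                   chrom = "chr1",
                   start = c(900, 100, 500), end = c(950, 150, 550))
  out <- assignOrdinals(df)
  expect_equal(out$gene_id[order(out$ordinal)], c("g1", "g2", "g3"))
  expect_equal(sort(out$ordinal), 1:3)
})

test_that("ordinal sequences are independent per chromosome and dense", {
  df <- data.frame(gene_id = paste0("g", 1:6),
                   chrom = rep(c("chr1", "chr2"), each = 3),
                   start = c(10, 20, 30, 5, 15, 25),
                   end = c(12, 22, 32, 7, 17, 27))
  out <- assignOrdinals(df)
  expect_equal(out$ordinal[out$chrom == "chr1"], 1:3)
  expect_equal(out$ordinal[out$chrom == "chr2"], 1:3)
})

test_that("gene order ties break by end then gene_id, and errors fire", {
  df <- data.frame(gene_id = c("b", "a"), chrom = "chr1",
                   start = c(100, 100), end = c(200, 200))
  out <- assignOrdinals(df)
  expect_equal(out$gene_id[order(out$ordinal)], c("a", "b"))
  expect_error(assignOrdinals(data.frame(gene_id = c("x", "x"),
                                         chrom = "c", start = 1, end = 2)),
               "duplicate")
  expect_error(assignOrdinals(data.frame(gene_id = "x", chrom = "c",
                                         start = 5, end = 2)), "start > end")
})

test_that("GFF3 input is read and collapsed to gene records", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gA",
               "chr1\tsrc\tmRNA\t100\t500\t.\t+\t.\tID=gA.1;Parent=gA",
               "chr1\tsrc\tgene\t900\t1200\t.\t-\t.\tID=gB"), gff)
  out <- readGeneOrder(gff)
  expect_equal(out$gene_id, c("gA", "gB"))
  expect_equal(out$ordinal, 1:2)
  expect_equal(out$strand, c("+", "-"))
})

test_that("genotype normalization equates phased/unphased and orderings", {
  expect_equal(normalizeGenotype("1/0"), "0/1")
  expect_equal(normalizeGenotype("0|1"), "0/1")
  expect_equal(normalizeGenotype(c("0/1", "1|0")), c("0/1", "0/1"))
  expect_true(is.na(normalizeGenotype("./.")))
  expect_true(is.na(normalizeGenotype(".")))
})

test_that("trio VCF reading surfaces genotypes, depths and INFO fields", {
  sim <- simulateTrio(20, c(0.4, 0.3, 0.2, 0.1), seed = 11,
                      vcfPath = file.path(tempdir(), "t.vcf"))
  rd <- readTrioVcf(file.path(tempdir(), "t.vcf"), "F1", "P1", "P2")
  expect_equal(nrow(rd), 20L)
  expect_equal(rd$gt_f1, sim$sites$gt_f1)
  expect_equal(rd$dp_p2, sim$sites$dp_p2)
  expect_equal(rd$QD, sim$sites$QD, tolerance = 1e-6)
})

test_that("naming an absent trio sample errors listing header samples", {
  p <- file.path(tempdir(), "t2.vcf")
  simulateTrio(5, c(1, 0, 0, 0), seed = 1, vcfPath = p)
  expect_error(readTrioVcf(p, "F1", "P1", "NOPE"), "P2")
})

test_that("missing genotypes and multiallelic records are handled", {
  p <- file.path(tempdir(), "t3.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1\tP1\tP2",
               "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT\t./.\t0/1\t0/0",
               "chr1\t200\t.\tA\tT,G\t50\tPASS\t.\tGT\t1/2\t0/1\t0/2"), p)
  rd <- readTrioVcf(p, "F1", "P1", "P2")
  expect_true(is.na(rd$gt_f1[1]))
  # multiallelic: one decomposed row per alternate
  expect_equal(sum(rd$pos == 200), 2L)
  r1 <- rd[rd$pos == 200 & rd$alt == "T", ]
  expect_true(is.na(r1$gt_f1))        # carries the other alt
  expect_equal(r1$gt_p1, "0/1")
})
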