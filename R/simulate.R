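# Synthetic-data generators. Each plants known truth for a downstream
# stage and is deterministic given (parameters, seed): class counts use
# largest-remainder allocation, never sampling, so expected counts are
# exact.

#' Deterministic largest-remainder allocation of counts
#'
#' Splits \code{n} into integer counts proportional to \code{fractions}:
#' floors plus one extra unit to the largest remainders (ties to the
#' earlier class). The result always sums to \code{n}.
#'
#' @param n total count.
#' @param fractions nonnegative, summing to 1 (within 1e-9).
#' @return integer vector, same names as \code{fractions}.
#' @export
largestRemainder <- function(n, fractions) {
  if (any(fractions < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  base <- floor(n * fractions)
  rem <- n * fractions - base
  short <- n - sum(base)
  if (short > 0) {
    up <- order(-rem, seq_along(rem))[seq_len(short)]
    base[up] <- base[up] + 1
  }
  out <- as.integer(base)
  names(out) <- names(fractions)
  out
}

# --- nested-list tree helpers (generator-internal) -----------------------

# species phylo -> nested list; leaves become taxon names
nestedFromSpecies <- function(g, node) {
  if (isTipNode(g, node)) return(g$taxon[node])
  lapply(g$children[[node]], function(k) nestedFromSpecies(g, k))
}

nestedLeaves <- function(nd) {
  if (!is.list(nd)) return(nd)
  unlist(lapply(nd, nestedLeaves), use.names = FALSE)
}

# rename leaves taxon -> "taxon|gene" with a copy tag
nestedLabel <- function(nd, fam, tag, delim = "|") {
  if (!is.list(nd)) return(paste0(nd, delim, fam, "_", nd, "_", tag))
  lapply(nd, function(x) nestedLabel(x, fam, tag, delim))
}

# keep only leaves in `keep`; collapse unary nodes; NULL when empty
nestedPrune <- function(nd, keep) {
  if (!is.list(nd)) return(if (nd %in% keep) nd else NULL)
  kids <- Filter(Negate(is.null), lapply(nd, function(x) nestedPrune(x, keep)))
  if (!length(kids)) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  kids
}

nestedToNewick <- function(nd, support = 100) {
  rec <- function(x) {
    if (!is.list(x)) return(x)
    paste0("(", paste(vapply(x, rec, ""), collapse = ","), ")", support)
  }
  paste0(rec(nd), ";")
}

# --- gene-tree generator -------------------------------------------------

#' Simulate gene-family trees with planted duplication events
#'
#' Each planted family's gene tree is the species tree with the subtree at
#' the requested species-tree node duplicated into two sister copies. For
#' class ABAB both copies keep the full subtree; for ABAX the second copy
#' is restricted to the node's first child lineage (A); for ABXB to the
#' second (B). Remaining families are single-copy trees congruent with
#' the species tree. Tips are then lost independently with probability
#' \code{lossProb}; at least two tips per tree are always retained. All
#' bipartition supports are written as 100.
#'
#' @param speciesTree rooted \code{ape::phylo} species tree.
#' @param nFamilies number of gene families.
#' @param dupSpec list of entries \code{list(node=, count=, class=)};
#'   \code{node} is a species-tree node id or a character vector of taxa
#'   (resolved by [lcaMap()]); \code{class} one of ABAB/ABAX/ABXB.
#' @param lossProb per-tip loss probability in \eqn{[0, 1)}.
#' @param seed integer seed; identical (parameters, seed) give
#'   byte-identical outputs.
#' @param dir when given, one Newick file per family plus a
#'   \code{truth.json} sidecar are written there.
#' @param delim leaf-label delimiter (taxon\code{delim}gene).
#' @return list with \code{newick} (named character vector),
#'   \code{trees} (named list of \code{"gtree"}), \code{truth}
#'   (data.frame: family, planted_node, planted_label, class, surviving
#'   copy species sets, detectable flag under the default two-shared-taxa
#'   rule, and placed_node for detectable events) and \code{params}.
#' @export
simulateGeneTrees <- function(speciesTree, nFamilies, dupSpec = list(),
                              lossProb = 0, seed = 1, dir = NULL,
                              delim = "|") {
  stopifnot(lossProb >= 0, lossProb < 1)
  prep <- prepSpeciesTree(speciesTree)
  g <- prep$g
  resolveNode <- function(nd) {
    if (is.numeric(nd)) return(as.integer(nd))
    lcaMap(nd, prep)
  }
  plant <- list()
  for (spec in dupSpec) {
    node <- resolveNode(spec$node)
    cls <- match.arg(spec$class, c("ABAB", "ABAX", "ABXB"))
    if (isTipNode(g, node))
      stop("cannot plant a ", cls, " duplication at a terminal node",
           call. = FALSE)
    kids <- g$children[[node]]
    if (length(kids) < 2L)
      stop("planted node must have two child lineages", call. = FALSE)
    cnt <- if (is.null(spec$count)) 1L else as.integer(spec$count)
    for (j in seq_len(cnt))
      plant[[length(plant) + 1L]] <- list(node = node, class = cls)
  }
  if (length(plant) > nFamilies)
    stop("more planted events than families", call. = FALSE)

  set.seed(seed)
  fullNested <- nestedFromSpecies(g, g$root)
  newick <- character(nFamilies)
  truthRows <- list()
  famIds <- sprintf("fam%04d", seq_len(nFamilies))

  for (i in seq_len(nFamilies)) {
    fam <- famIds[i]
    if (i <= length(plant)) {
      node <- plant[[i]]$node
      cls <- plant[[i]]$class
      kids <- g$children[[node]]
      sub <- nestedFromSpecies(g, node)
      copy2src <- switch(cls,
        ABAB = sub,
        ABAX = nestedFromSpecies(g, kids[1L]),
        ABXB = nestedFromSpecies(g, kids[2L]))
      copy1 <- nestedLabel(sub, fam, "c1", delim)
      copy2 <- nestedLabel(copy2src, fam, "c2", delim)
      dupNode <- list(copy1, copy2)
      tree <- replaceAtSpeciesNode(g, g$root, node, dupNode, fam, delim)
    } else {
      node <- NA_integer_; cls <- NA_character_
      tree <- nestedLabel(fullNested, fam, "s1", delim)
    }
    leaves <- nestedLeaves(tree)
    keep <- leaves
    if (lossProb > 0) {
      u <- stats::runif(length(leaves))
      keep <- leaves[u >= lossProb]
      if (length(keep) < 2L)            # keep trees non-degenerate
        keep <- leaves[order(u)][1:2]
      tree <- nestedPrune(tree, keep)
    }
    newick[i] <- if (is.list(tree)) nestedToNewick(tree) else
      paste0("(", tree, ");")

    if (!is.na(node)) {
      leafTaxon <- function(lv) sub(paste0("\\", delim, ".*$"), "", lv)
      isCopy2 <- grepl("_c2$", keep)
      isCopy1 <- grepl("_c1$", keep) &
        vapply(keep, function(lv)
          leafTaxon(lv) %in% prep$leafSets[[node]], logical(1))
      sL <- unique(leafTaxon(keep[isCopy1]))
      sR <- unique(leafTaxon(keep[isCopy2]))
      shared <- intersect(sL, sR)
      detectable <- length(shared) >= 2L
      placed <- if (detectable) lcaMap(union(sL, sR), prep) else NA_integer_
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        family = fam, planted_node = node,
        planted_label = speciesNodeLabel(node, prep), class = cls,
        survL = paste(sort(sL), collapse = ","),
        survR = paste(sort(sR), collapse = ","),
        detectable = detectable, placed_node = placed,
        stringsAsFactors = FALSE)
    }
  }
  names(newick) <- famIds
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(family = character(), planted_node = integer(),
               planted_label = character(), class = character(),
               survL = character(), survR = character(),
               detectable = logical(), placed_node = integer(),
               stringsAsFactors = FALSE)
  params <- list(nFamilies = nFamilies, lossProb = lossProb, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(nFamilies))
      writeLines(newick[i], file.path(dir, paste0(famIds[i], ".nwk")))
    jsonlite::write_json(list(params = params, truth = truth),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  trees <- lapply(newick, readTree, delim = delim)
  list(newick = newick, trees = trees, truth = truth, params = params)
}

# rebuild the species nested tree, substituting `repl` at species node
# `target`; other leaves get single-copy labels
replaceAtSpeciesNode <- function(g, node, target, repl, fam, delim) {
  if (node == target) return(repl)
  if (isTipNode(g, node))
    return(nestedLabel(g$taxon[node], fam, "s1", delim))
  lapply(g$children[[node]], function(k)
    replaceAtSpeciesNode(g, k, target, repl, fam, delim))
}

# --- codon-pair generator ------------------------------------------------

#' Simulate a codon-aligned pair with known substitution counts
#'
#' Starts from a random stop-free codon sequence and introduces exactly
#' \code{nSyn} synonymous and \code{nNonsyn} nonsynonymous single-
#' nucleotide substitutions, at most one per codon, never creating a stop
#' codon. By construction the Nei-Gojobori difference counts on the pair
#' are exactly \code{Sd = nSyn}, \code{Nd = nNonsyn}.
#'
#' @param nCodons alignment length in codons.
#' @param nSyn,nNonsyn numbers of synonymous / nonsynonymous changes.
#' @param seed integer seed.
#' @param fastaPath optional path; the two sequences are written there as
#'   FASTA (ids \code{seq1}, \code{seq2}).
#' @return list with \code{seq1}, \code{seq2} (character strings) and
#'   \code{truth} (nSyn, nNonsyn and the 1-based codon indices used).
#' @export
simulateCodonPair <- function(nCodons, nSyn, nNonsyn, seed = 1,
                              fastaPath = NULL) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- senseCodons(code)
  cods <- sample(sense, nCodons, replace = TRUE)

  optionsOf <- function(codon, synonymous) {
    nt <- strsplit(codon, "")[[1L]]
    out <- list()
    for (pos in 1:3) for (b in setdiff(BASES, nt[pos])) {
      mut <- nt; mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (code[[mc]] == "*") next
      if ((code[[mc]] == code[[codon]]) == synonymous)
        out[[length(out) + 1L]] <- mc
    }
    out
  }
  hasSyn <- vapply(cods, function(cd) length(optionsOf(cd, TRUE)) > 0,
                   logical(1))
  hasNon <- vapply(cods, function(cd) length(optionsOf(cd, FALSE)) > 0,
                   logical(1))
  if (sum(hasSyn) < nSyn)
    stop("insufficient eligible synonymous sites (", sum(hasSyn),
         " available)", call. = FALSE)
  synIdx <- sample(which(hasSyn), nSyn)
  pool <- setdiff(which(hasNon), synIdx)
  if (length(pool) < nNonsyn)
    stop("insufficient eligible nonsynonymous sites (", length(pool),
         " available)", call. = FALSE)
  nonIdx <- if (nNonsyn > 0) sample(pool, nNonsyn) else integer(0)

  cods2 <- cods
  for (i in synIdx) {
    opt <- optionsOf(cods[i], TRUE)
    cods2[i] <- opt[[sample.int(length(opt), 1L)]]
  }
  for (i in nonIdx) {
    opt <- optionsOf(cods[i], FALSE)
    cods2[i] <- opt[[sample.int(length(opt), 1L)]]
  }
  seq1 <- paste(cods, collapse = "")
  seq2 <- paste(cods2, collapse = "")
  if (!is.null(fastaPath)) {
    ss <- Biostrings::DNAStringSet(c(seq1 = seq1, seq2 = seq2))
    Biostrings::writeXStringSet(ss, fastaPath)
  }
  list(seq1 = seq1, seq2 = seq2,
       truth = list(nSyn = nSyn, nNonsyn = nNonsyn,
                    synCodons = sort(synIdx), nonsynCodons = sort(nonIdx)))
}

# --- trio generator ------------------------------------------------------

#' Simulate trio genotype sites with planted inheritance classes
#'
#' Class counts follow the exact largest-remainder allocation of
#' \code{fractions} over (inherited_P1, inherited_P2, shared, de_novo) --
#' deterministic, not multinomial. Per-sample depths are
#' Poisson(\code{meanDepth}); INFO annotations are drawn inside the
#' hard-filter pass region.
#'
#' @param nSites number of variant sites (> 0).
#' @param fractions length-4 nonnegative vector summing to 1, ordered
#'   (inherited_P1, inherited_P2, shared, de_novo).
#' @param meanDepth mean sequencing depth (Poisson rate).
#' @param seed integer seed.
#' @param vcfPath optional path; a VCF v4.2 with samples F1, P1, P2 is
#'   written there (byte-identical for identical parameters and seed).
#' @return list with \code{sites} (data.frame: chrom, pos, ref, alt,
#'   gt_f1/gt_p1/gt_p2, dp_*, INFO columns, af, true_class) and
#'   \code{counts}.
#' @export
simulateTrio <- function(nSites, fractions = c(0.4, 0.3, 0.2, 0.1),
                         meanDepth = 30, seed = 1, vcfPath = NULL) {
  if (nSites <= 0) stop("nSites must be positive", call. = FALSE)
  stopifnot(length(fractions) == 4L)
  classes <- c("inherited_P1", "inherited_P2", "shared", "de_novo")
  counts <- largestRemainder(nSites, stats::setNames(fractions, classes))
  set.seed(seed)
  lab <- sample(rep(classes, counts))

  tmpl <- list(
    inherited_P1 = list(c("0/1", "0/1", "0/0"), c("1/1", "1/1", "0/1"),
                        c("0/1", "0/1", "1/1")),
    inherited_P2 = list(c("0/1", "0/0", "0/1"), c("1/1", "0/1", "1/1"),
                        c("0/1", "1/1", "0/1")),
    shared = list(c("0/1", "0/1", "0/1"), c("1/1", "1/1", "1/1")),
    de_novo = list(c("1/1", "0/0", "0/1"), c("0/1", "0/0", "0/0"),
                   c("1/1", "0/1", "0/1")))

  refs <- sample(BASES, nSites, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(BASES, r), 1L), "")
  gts <- t(vapply(lab, function(cl) {
    t <- tmpl[[cl]]
    t[[sample.int(length(t), 1L)]]
  }, character(3)))
  dp <- matrix(stats::rpois(3L * nSites, meanDepth), ncol = 3L)
  qd <- round(stats::runif(nSites, 15, 35), 2)
  fs <- round(stats::runif(nSites, 0, 10), 3)
  mq <- round(stats::runif(nSites, 50, 60), 2)
  sor <- round(stats::runif(nSites, 0.3, 2), 3)

  dosage <- function(gt) vapply(strsplit(gt, "/"), function(a)
    sum(a == "1"), numeric(1))
  af <- (dosage(gts[, 1L]) + dosage(gts[, 2L]) + dosage(gts[, 3L])) / 6

  sites <- data.frame(
    chrom = "chr1", pos = 100L * seq_len(nSites),
    ref = refs, alt = alts,
    gt_f1 = gts[, 1L], gt_p1 = gts[, 2L], gt_p2 = gts[, 3L],
    dp_f1 = dp[, 1L], dp_p1 = dp[, 2L], dp_p2 = dp[, 3L],
    QD = qd, FS = fs, MQ = mq, SOR = sor,
    MQRankSum = 0, ReadPosRankSum = 0,
    DP = rowSums(dp), af = af, true_class = lab,
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL

  if (!is.null(vcfPath)) writeTrioVcf(sites, vcfPath)
  list(sites = sites, counts = counts,
       params = list(nSites = nSites, fractions = fractions,
                     meanDepth = meanDepth, seed = seed))
}

writeTrioVcf <- function(sites, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"SymmetricOddsRatio\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQRankSum\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSum\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1\tP1\tP2")
  body <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    info <- sprintf("QD=%.2f;FS=%.3f;MQ=%.2f;SOR=%.3f;MQRankSum=%.1f;ReadPosRankSum=%.1f;DP=%d",
                    s$QD, s$FS, s$MQ, s$SOR, s$MQRankSum, s$ReadPosRankSum,
                    as.integer(s$DP))
    paste(s$chrom, s$pos, ".", s$ref, s$alt, "100", "PASS", info, "GT:DP",
          paste0(s$gt_f1, ":", s$dp_f1), paste0(s$gt_p1, ":", s$dp_p1),
          paste0(s$gt_p2, ":", s$dp_p2), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

# --- expression generator ------------------------------------------------

#' Simulate parent/F1 expression triplets with planted inheritance modes
#'
#' Parental means differ by factor \code{fold} (which parent is high is
#' randomized per gene); the F1 mean is placed per planted mode: A at the
#' mid-parent, PD at the high parent, ND at the low parent, PPD at the
#' geometric midpoint of mid and high parent, NPD at the geometric
#' midpoint of low and mid parent (the geometric midpoint splits the
#' planted effect evenly on the log scale, where the lognormal replicate
#' noise and the downstream tests live), POD at \code{fold} times the
#' high parent, NOD at the low parent divided by \code{fold}. Replicate
#' noise is lognormal, mean-preserving, with coefficient of variation
#' \code{cv}.
#'
#' @param nGenes number of genes.
#' @param modeMix named fractions over A, PD, ND, PPD, NPD, POD, NOD
#'   (must sum to 1); allocated by largest remainder.
#' @param fold parental fold change (>= 1).
#' @param nReps replicates per group (>= 2).
#' @param cv replicate coefficient of variation (>= 0; 0 = noise-free).
#' @param baseTPM low-parent mean expression (default 100 TPM).
#' @param seed integer seed.
#' @param path optional TSV output (genes x P1_*/P2_*/F1_* columns).
#' @return list with \code{tpm} (matrix), \code{truth} (gene_id, mode,
#'   high_parent), column index vectors \code{p1Cols}/\code{p2Cols}/
#'   \code{f1Cols}, and \code{params}.
#' @export
simulateExpression <- function(nGenes, modeMix = c(A = 1), fold = 2,
                               nReps = 3, cv = 0.1, baseTPM = 100,
                               seed = 1, path = NULL) {
  modes <- c("A", "PD", "ND", "PPD", "NPD", "POD", "NOD")
  if (nReps < 2) stop("nReps must be >= 2", call. = FALSE)
  if (cv < 0) stop("cv must be nonnegative", call. = FALSE)
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  if (!all(names(modeMix) %in% modes))
    stop("unknown mode in modeMix", call. = FALSE)
  mix <- stats::setNames(numeric(length(modes)), modes)
  mix[names(modeMix)] <- modeMix
  counts <- largestRemainder(nGenes, mix)
  set.seed(seed)
  lab <- sample(rep(modes, counts))
  highP1 <- stats::runif(nGenes) < 0.5

  lp <- baseTPM
  hp <- baseTPM * fold
  mp <- (lp + hp) / 2
  f1Mean <- vapply(lab, function(m) switch(m,
    A = mp, PD = hp, ND = lp, PPD = sqrt(mp * hp), NPD = sqrt(lp * mp),
    POD = hp * fold, NOD = lp / fold), numeric(1))

  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noisy <- function(m, n) {
    if (sdlog == 0) return(rep(m, n))
    m * exp(stats::rnorm(n, 0, sdlog)) / exp(sdlog^2 / 2)
  }
  tpm <- matrix(NA_real_, nGenes, 3L * nReps)
  colnames(tpm) <- c(paste0("P1_", seq_len(nReps)),
                     paste0("P2_", seq_len(nReps)),
                     paste0("F1_", seq_len(nReps)))
  rownames(tpm) <- sprintf("gene%05d", seq_len(nGenes))
  for (i in seq_len(nGenes)) {
    mP1 <- if (highP1[i]) hp else lp
    mP2 <- if (highP1[i]) lp else hp
    tpm[i, ] <- c(noisy(mP1, nReps), noisy(mP2, nReps),
                  noisy(f1Mean[i], nReps))
  }
  truth <- data.frame(gene_id = rownames(tpm), mode = lab,
                      high_parent = ifelse(highP1, "P1", "P2"),
                      stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(data.frame(gene_id = rownames(tpm), tpm,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(tpm = tpm, truth = truth,
       p1Cols = seq_len(nReps), p2Cols = nReps + seq_len(nReps),
       f1Cols = 2L * nReps + seq_len(nReps),
       params = list(nGenes = nGenes, modeMix = mix, fold = fold,
                     nReps = nReps, cv = cv, seed = seed))
}
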