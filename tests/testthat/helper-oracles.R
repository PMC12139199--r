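# Independent brute-force oracles. These deliberately avoid the package's
# internal tree representation and codon tables: trees are walked on raw
# ape edge matrices, LCA mappings are found by scanning every species-tree
# node, and substitution pathways are enumerated by depth-first recursion.

# ---- reconciliation oracle ---------------------------------------------

oracleTipsUnder <- function(phy, v) {
  nTip <- length(phy$tip.label)
  if (v <= nTip) return(phy$tip.label[v])
  kids <- phy$edge[phy$edge[, 1L] == v, 2L]
  unlist(lapply(kids, function(k) oracleTipsUnder(phy, k)))
}

# per-node taxon sets of a species tree (labels are bare taxa)
oracleSpeciesSets <- function(st) {
  n <- length(st$tip.label) + st$Nnode
  lapply(seq_len(n), function(v) unique(oracleTipsUnder(st, v)))
}

# brute-force LCA mapping: the species node with the smallest leaf set
# containing all taxa (scans every node)
oracleMapNode <- function(taxa, sets) {
  cand <- which(vapply(sets, function(s) all(taxa %in% s), logical(1)))
  cand[which.min(lengths(sets)[cand])]
}

oracleDepths <- function(st) {
  n <- length(st$tip.label) + st$Nnode
  root <- setdiff(unique(st$edge[, 1L]), st$edge[, 2L])
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(st$edge))) {
      p <- st$edge[i, 1L]; c <- st$edge[i, 2L]
      if (!is.na(depth[p]) && is.na(depth[c])) {
        depth[c] <- depth[p] + 1L; done <- FALSE
      }
    }
    if (done) break
  }
  depth
}

# duplication + loss score of a rooted gene tree (ape phylo, tips
# "taxon|gene") against a species tree
oracleReconcileScore <- function(phy, st) {
  sets <- oracleSpeciesSets(st)
  depth <- oracleDepths(st)
  nTip <- length(phy$tip.label)
  nAll <- nTip + phy$Nnode
  taxaOf <- function(v) unique(sub("\\|.*$", "", oracleTipsUnder(phy, v)))
  M <- vapply(seq_len(nAll), function(v) oracleMapNode(taxaOf(v), sets),
              integer(1))
  internals <- unique(phy$edge[, 1L])
  dups <- 0L; losses <- 0L
  for (v in internals) {
    kids <- phy$edge[phy$edge[, 1L] == v, 2L]
    isDup <- any(M[kids] == M[v])
    dups <- dups + as.integer(isDup)
    for (k in kids)
      losses <- losses + (depth[M[k]] - depth[M[v]]) - 1L + as.integer(isDup)
  }
  list(dups = dups, losses = losses, score = dups + losses, M = M)
}

# minimum reconciliation score over every rooting of the (unrooted
# version of the) gene tree; rootings enumerated via ape::root on every
# possible outgroup-side tip set
oracleMinRootScore <- function(phy, st) {
  uphy <- ape::unroot(phy)
  nTip <- length(uphy$tip.label)
  best <- Inf; bestDups <- Inf
  for (v in uphy$edge[, 2L]) {
    og <- oracleTipsUnder(uphy, v)
    if (length(og) == nTip) next
    rphy <- tryCatch(ape::root(uphy, outgroup = og, resolve.root = TRUE),
                     error = function(e) NULL)
    if (is.null(rphy)) next
    sc <- oracleReconcileScore(rphy, st)
    if (sc$score < best || (sc$score == best && sc$dups < bestDups)) {
      best <- sc$score; bestDups <- sc$dups
    }
  }
  list(score = best, dups = bestDups)
}

# independent duplication detection on a rooted ape phylo: walks clades
# via the edge matrix and applies the shared-species / support rules
oracleDetect <- function(phy, st, bp = 70, subBp = 70, minShared = 2) {
  sets <- oracleSpeciesSets(st)
  sup <- function(v) {
    nTip <- length(phy$tip.label)
    if (v <= nTip || is.null(phy$node.label)) return(NA_real_)
    suppressWarnings(as.numeric(phy$node.label[v - nTip]))
  }
  out <- integer(0)
  for (v in unique(phy$edge[, 1L])) {
    kids <- phy$edge[phy$edge[, 1L] == v, 2L]
    if (length(kids) != 2L) next
    tx <- lapply(kids, function(k)
      unique(sub("\\|.*$", "", oracleTipsUnder(phy, k))))
    if (length(intersect(tx[[1L]], tx[[2L]])) < minShared) next
    pass <- function(s, thr) is.na(s) || s >= thr
    if (!pass(sup(v), bp)) next
    if (!pass(sup(kids[1L]), subBp) || !pass(sup(kids[2L]), subBp)) next
    out <- c(out, oracleMapNode(union(tx[[1L]], tx[[2L]]), sets))
  }
  out
}

# ---- NG86 oracle --------------------------------------------------------

oracleCode <- Biostrings::GENETIC_CODE

oracleSiteCounts <- function(codon) {
  aa <- oracleCode[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracleCode[[mut]] != "*" && oracleCode[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(s, 3 - s)
}

# depth-first enumeration of substitution pathways between two codons;
# returns matrix with columns sd, nd, valid
oraclePaths <- function(c1, c2) {
  res <- list()
  walk <- function(cur, sd, nd, hitStop) {
    if (cur == c2) {
      res[[length(res) + 1L]] <<- c(sd = sd, nd = nd, valid = !hitStop)
      return(invisible())
    }
    for (pos in 1:3) {
      if (substr(cur, pos, pos) == substr(c2, pos, pos)) next
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      syn <- oracleCode[[cur]] != "*" && oracleCode[[nxt]] != "*" &&
        oracleCode[[cur]] == oracleCode[[nxt]]
      walk(nxt, sd + as.integer(syn), nd + as.integer(!syn),
           hitStop || (oracleCode[[nxt]] == "*" && nxt != c2))
    }
  }
  walk(c1, 0L, 0L, FALSE)
  do.call(rbind, res)
}

oracleNG86 <- function(s1, s2) {
  n <- nchar(s1) / 3
  starts <- 3 * seq_len(n) - 2
  c1 <- substring(s1, starts, starts + 2)
  c2 <- substring(s2, starts, starts + 2)
  ok <- function(cs) grepl("^[ACGT]{3}$", cs) & cs %in% names(oracleCode) &
    oracleCode[cs] != "*"
  keep <- ok(c1) & ok(c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  S <- mean(c(sum(vapply(c1, function(x) oracleSiteCounts(x)[1], 0)),
              sum(vapply(c2, function(x) oracleSiteCounts(x)[1], 0))))
  N <- 3 * length(c1) - S
  Sd <- Nd <- 0
  for (i in which(c1 != c2)) {
    pm <- oraclePaths(c1[i], c2[i])
    use <- if (any(pm[, "valid"] == 1)) pm[, "valid"] == 1 else
      rep(TRUE, nrow(pm))
    Sd <- Sd + mean(pm[use, "sd"])
    Nd <- Nd + mean(pm[use, "nd"])
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  pS <- Sd / S; pN <- Nd / N
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ka = jc(pN), Ks = jc(pS))
}

# random stop-free coding sequence pair with arbitrary (multi-hit) diffs
randomCodingPair <- function(nCodons, pDiff = 0.05) {
  sense <- names(oracleCode)[oracleCode != "*"]
  c1 <- sample(sense, nCodons, replace = TRUE)
  c2 <- vapply(c1, function(cd) {
    if (stats::runif(1) < pDiff) sample(sense, 1L) else cd
  }, "")
  list(paste(c1, collapse = ""), paste(c2, collapse = ""))
}
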