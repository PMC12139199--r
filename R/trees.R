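# Internal rooted-tree representation used by the reconciliation engine.
#
# A "gtree" keeps, for every node, the support of the edge ABOVE it (the
# bipartition support printed as the node label in Newick), so supports
# survive re-rooting, which is not true of naive node-label bookkeeping.

# Build a gtree from an ape::phylo object. Leaf labels are parsed into
# (taxon, gene) under `delim`; pass delim = NA to keep labels as bare taxa
# (species trees).
asGtree <- function(phy, delim = "|") {
  stopifnot(inherits(phy, "phylo"))
  nTip <- length(phy$tip.label)
  nTot <- nTip + phy$Nnode
  parent <- rep(NA_integer_, nTot)
  children <- vector("list", nTot)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- which(is.na(parent) & seq_len(nTot) > nTip)
  if (length(root) != 1L) root <- nTip + 1L

  len <- rep(NA_real_, nTot)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2L]] <- phy$edge.length

  support <- rep(NA_real_, nTot)
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    support[nTip + seq_len(phy$Nnode)] <- sup
    ok <- !is.na(support)
    if (any(ok) && all(support[ok] >= 0 & support[ok] <= 1)) {
      support[ok] <- support[ok] * 100
      warning("supports look like proportions in [0,1]; rescaled to 0-100",
              call. = FALSE)
    }
    if (any(support[ok] < 0 | support[ok] > 100))
      stop("node supports outside [0,100] after scaling", call. = FALSE)
  }

  taxon <- gene <- rep(NA_character_, nTot)
  label <- rep(NA_character_, nTot)
  label[seq_len(nTip)] <- phy$tip.label
  if (!is.na(delim)) {
    for (i in seq_len(nTip)) {
      parts <- strsplit(phy$tip.label[i], delim, fixed = TRUE)[[1L]]
      if (length(parts) < 2L)
        stop("leaf label '", phy$tip.label[i],
             "' does not parse under schema taxon", delim, "gene",
             call. = FALSE)
      taxon[i] <- parts[1L]
      gene[i] <- paste(parts[-1L], collapse = delim)
    }
  } else {
    taxon[seq_len(nTip)] <- phy$tip.label
    gene[seq_len(nTip)] <- phy$tip.label
  }

  structure(list(nTip = nTip, nNode = nTot, parent = parent,
                 children = children, root = root, label = label,
                 taxon = taxon, gene = gene, support = support,
                 length = len, delim = delim),
            class = "gtree")
}

isTipNode <- function(gt, v) v <= gt$nTip

# Postorder node sequence (children before parents).
postorderNodes <- function(gt) {
  out <- integer(0)
  stack <- gt$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(v, out)
    stack <- c(stack, gt$children[[v]])
  }
  out
}

# Taxa (possibly repeated) under each node; list indexed by node id.
nodeTaxa <- function(gt) {
  taxa <- vector("list", gt$nNode)
  for (v in postorderNodes(gt)) {
    if (isTipNode(gt, v)) taxa[[v]] <- gt$taxon[v]
    else taxa[[v]] <- unlist(taxa[gt$children[[v]]], use.names = FALSE)
  }
  taxa
}

gtreeToNewick <- function(gt, digits = 6) {
  rec <- function(v) {
    if (isTipNode(gt, v)) s <- gt$label[v]
    else {
      s <- paste0("(", paste(vapply(gt$children[[v]], rec, ""),
                             collapse = ","), ")")
      if (v != gt$root && !is.na(gt$support[v]))
        s <- paste0(s, format(gt$support[v], digits = digits))
      if (v == gt$root && !is.na(gt$support[v]))
        s <- paste0(s, format(gt$support[v], digits = digits))
    }
    if (!is.na(gt$length[v])) s <- paste0(s, ":", format(gt$length[v],
                                                         digits = digits))
    s
  }
  paste0(rec(gt$root), ";")
}

# Undirected edge table of the unrooted version of gt. A binary root is
# suppressed (its two incident edges merge into one). Columns: a, b,
# length, support. Each row is a candidate root position.
unrootedEdges <- function(gt) {
  rows <- list()
  kids <- gt$children[[gt$root]]
  if (length(kids) == 2L) {
    lsum <- if (all(is.na(gt$length[kids]))) NA_real_
            else sum(gt$length[kids], na.rm = TRUE)
    sup <- gt$support[kids]
    sup <- if (all(is.na(sup))) NA_real_ else max(sup, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- list(a = kids[1L], b = kids[2L],
                                      length = lsum, support = sup)
    skip <- kids
  } else skip <- integer(0)
  for (v in seq_len(gt$nNode)) {
    if (v == gt$root || v %in% skip) next
    if (is.na(gt$parent[v])) next
    rows[[length(rows) + 1L]] <- list(a = gt$parent[v], b = v,
                                      length = gt$length[v],
                                      support = gt$support[v])
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

# Re-root the unrooted version of gt on edge row i of unrootedEdges(gt).
# Returns a new gtree whose root is a fresh binary node on that edge.
rerootAtEdge <- function(gt, edges, i) {
  nOld <- gt$nNode
  rootNew <- nOld + 1L
  # undirected adjacency with per-edge attributes
  adj <- vector("list", rootNew)
  addEdge <- function(a, b, len, sup) {
    adj[[a]][[length(adj[[a]]) + 1L]] <<- list(to = b, len = len, sup = sup)
    adj[[b]][[length(adj[[b]]) + 1L]] <<- list(to = a, len = len, sup = sup)
  }
  for (j in seq_len(nrow(edges))) {
    if (j == i) next
    addEdge(edges$a[j], edges$b[j], edges$length[j], edges$support[j])
  }
  half <- if (is.na(edges$length[i])) NA_real_ else edges$length[i] / 2
  addEdge(rootNew, edges$a[i], half, edges$support[i])
  addEdge(rootNew, edges$b[i], half, edges$support[i])

  parent <- rep(NA_integer_, rootNew)
  children <- vector("list", rootNew)
  support <- rep(NA_real_, rootNew)
  len <- rep(NA_real_, rootNew)
  # orient away from rootNew
  stack <- rootNew
  seen <- logical(rootNew); seen[rootNew] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (e in adj[[v]]) {
      w <- e$to
      if (seen[w]) next
      seen[w] <- TRUE
      parent[w] <- v
      children[[v]] <- c(children[[v]], w)
      support[w] <- e$sup
      len[w] <- e$len
      stack <- c(stack, w)
    }
  }
  structure(list(nTip = gt$nTip, nNode = rootNew, parent = parent,
                 children = children, root = rootNew,
                 label = c(gt$label, NA_character_),
                 taxon = c(gt$taxon, NA_character_),
                 gene = c(gt$gene, NA_character_),
                 support = support, length = len, delim = gt$delim),
            class = "gtree")
}
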