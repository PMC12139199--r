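# Species-tree preparation, LCA mapping, duplication/loss reconciliation,
# min-score rooting and duplication detection.

# Precompute parent pointers, depths and tip lookup for a rooted species
# tree (ape phylo). Depth 0 at the root.
prepSpeciesTree <- function(st) {
  stopifnot(inherits(st, "phylo"))
  if (!ape::is.rooted(st)) stop("species tree must be rooted", call. = FALSE)
  gt <- asGtree(st, delim = NA)
  depth <- rep(NA_integer_, gt$nNode)
  depth[gt$root] <- 0L
  for (v in rev(postorderNodes(gt)))  # preorder
    if (v != gt$root) depth[v] <- depth[gt$parent[v]] + 1L
  tipOf <- seq_len(gt$nTip)
  names(tipOf) <- gt$taxon[seq_len(gt$nTip)]
  leafSets <- nodeTaxa(gt)
  list(tree = st, g = gt, depth = depth, tipOf = tipOf,
       leafSets = lapply(leafSets, unique))
}

lcaPair <- function(prep, a, b) {
  da <- prep$depth[a]; db <- prep$depth[b]
  while (da > db) { a <- prep$g$parent[a]; da <- da - 1L }
  while (db > da) { b <- prep$g$parent[b]; db <- db - 1L }
  while (a != b) { a <- prep$g$parent[a]; b <- prep$g$parent[b] }
  a
}

#' Map a set of taxa to its species-tree MRCA
#'
#' Returns the lowest species-tree node whose leaf set contains all the
#' given taxa (the LCA mapping used for gene-tree/species-tree
#' reconciliation).
#'
#' @param taxa character vector of taxon ids (a gene-tree clade's species
#'   content).
#' @param speciesTree rooted \code{ape::phylo} species tree, or a
#'   prepared species tree from previous calls.
#' @return internal node id of the species tree (tip id for a single
#'   taxon); the label is available via [speciesNodeLabel()].
#' @export
lcaMap <- function(taxa, speciesTree) {
  prep <- if (inherits(speciesTree, "phylo")) prepSpeciesTree(speciesTree)
          else speciesTree
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, names(prep$tipOf))
  if (length(unknown))
    stop("taxon not in species tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ids <- unname(prep$tipOf[taxa])
  v <- ids[1L]
  for (w in ids[-1L]) v <- lcaPair(prep, v, w)
  v
}

#' Human-readable label for a species-tree node
#'
#' The node's own label when present, otherwise \code{MRCA(taxon,taxon,...)}.
#' @param node species-tree node id.
#' @param prep prepared species tree (or a \code{phylo}).
#' @export
speciesNodeLabel <- function(node, prep) {
  if (inherits(prep, "phylo")) prep <- prepSpeciesTree(prep)
  g <- prep$g
  if (node <= g$nTip) return(g$taxon[node])
  if (!is.na(g$label[node]) && nzchar(g$label[node])) return(g$label[node])
  paste0("MRCA(", paste(sort(prep$leafSets[[node]]), collapse = ","), ")")
}

# LCA reconciliation of a rooted gene tree against a prepared species
# tree. Returns per-node mapping M, duplication flags and the standard
# duplication/loss counts (losses from depth differences along mapped
# edges: for an edge v -> c, losses = depth(M(c)) - depth(M(v)) - 1,
# plus 1 when v is a duplication).
reconcileTree <- function(gt, prep) {
  ord <- postorderNodes(gt)
  M <- rep(NA_integer_, gt$nNode)
  isDup <- rep(FALSE, gt$nNode)
  for (v in ord) {
    if (isTipNode(gt, v)) {
      tax <- gt$taxon[v]
      if (!tax %in% names(prep$tipOf))
        stop("taxon not in species tree: ", tax, call. = FALSE)
      M[v] <- prep$tipOf[[tax]]
    } else {
      kids <- gt$children[[v]]
      m <- M[kids[1L]]
      for (k in kids[-1L]) m <- lcaPair(prep, m, M[k])
      M[v] <- m
      isDup[v] <- any(M[kids] == m)
    }
  }
  losses <- 0L
  for (v in ord) {
    if (isTipNode(gt, v)) next
    for (c in gt$children[[v]]) {
      d <- prep$depth[M[c]] - prep$depth[M[v]]
      losses <- losses + d - 1L + as.integer(isDup[v])
    }
  }
  list(M = M, isDup = isDup, dups = sum(isDup), losses = losses,
       score = sum(isDup) + losses)
}

#' Root a gene tree against the species tree
#'
#' Evaluates every branch of the unrooted gene tree as a root position and
#' keeps the rooting minimizing duplications + losses under LCA
#' reconciliation. Ties are broken deterministically: fewer duplications,
#' then the rooting whose outgroup-side clade maps deepest in the species
#' tree (closest to its root), then the lexicographically smallest leaf
#' label on the outgroup side.
#'
#' @param gt gene tree (\code{"gtree"} from [readTree()]), rooted
#'   arbitrarily or not.
#' @param speciesTree rooted species tree (\code{phylo} or prepared).
#' @return the re-rooted \code{"gtree"}, with attributes \code{score},
#'   \code{dups}, \code{losses} of the chosen rooting.
#' @export
rootGeneTree <- function(gt, speciesTree) {
  prep <- if (inherits(speciesTree, "phylo")) prepSpeciesTree(speciesTree)
          else speciesTree
  if (gt$nTip < 3L) {
    rec <- reconcileTree(gt, prep)
    attr(gt, "score") <- rec$score
    attr(gt, "dups") <- rec$dups
    attr(gt, "losses") <- rec$losses
    return(gt)
  }
  edges <- unrootedEdges(gt)
  best <- NULL
  for (i in seq_len(nrow(edges))) {
    cand <- rerootAtEdge(gt, edges, i)
    rec <- reconcileTree(cand, prep)
    kids <- cand$children[[cand$root]]
    kd <- prep$depth[rec$M[kids]]
    minLab <- vapply(kids, function(k) {
      taxa <- sort(gt$label[tipsUnder(cand, k)])
      taxa[1L]
    }, character(1))
    og <- if (kd[1L] != kd[2L]) which.min(kd) else which.min(rank(minLab))
    key <- list(score = rec$score, dups = rec$dups,
                ogDepth = kd[og], ogLab = minLab[og], idx = i)
    if (is.null(best) || lessKey(key, best$key))
      best <- list(key = key, tree = cand, rec = rec)
  }
  out <- best$tree
  attr(out, "score") <- best$rec$score
  attr(out, "dups") <- best$rec$dups
  attr(out, "losses") <- best$rec$losses
  out
}

tipsUnder <- function(gt, v) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (isTipNode(gt, x)) out <- c(out, x)
    else stack <- c(stack, gt$children[[x]])
  }
  out
}

lessKey <- function(a, b) {
  if (a$score != b$score) return(a$score < b$score)
  if (a$dups != b$dups) return(a$dups < b$dups)
  if (a$ogDepth != b$ogDepth) return(a$ogDepth < b$ogDepth)
  if (a$ogLab != b$ogLab) return(a$ogLab < b$ogLab)
  a$idx < b$idx
}

#' Detect gene-duplication events on a rooted gene tree
#'
#' A gene-tree node is called a duplication event when the species sets of
#' its two child clades share at least \code{minShared} taxa, the node's
#' bipartition support is at least \code{bp}, and both child supports are
#' at least \code{subBp}. Missing supports pass (absence of a bootstrap is
#' treated as uninformative, not as 0). The event is placed on the species
#' tree at the LCA mapping of the node.
#'
#' @param gt rooted gene tree (\code{"gtree"}).
#' @param speciesTree rooted species tree (\code{phylo} or prepared).
#' @param bp node support threshold (default 70).
#' @param subBp child support threshold (default 70).
#' @param minShared minimum number of taxa shared by the two child clades
#'   (default 2).
#' @param family family id recorded with each event.
#' @return a [GDEventSet-class].
#' @export
detectDuplications <- function(gt, speciesTree, bp = 70, subBp = 70,
                               minShared = 2, family = "fam") {
  prep <- if (inherits(speciesTree, "phylo")) prepSpeciesTree(speciesTree)
          else speciesTree
  taxa <- nodeTaxa(gt)
  rows <- list()
  for (v in postorderNodes(gt)) {
    if (isTipNode(gt, v)) next
    kids <- gt$children[[v]]
    if (length(kids) < 2L) next
    # for (rare) polytomies take the child pair with maximal species overlap
    pairIdx <- if (length(kids) == 2L) c(1L, 2L) else {
      cmb <- utils::combn(seq_along(kids), 2L)
      ov <- apply(cmb, 2L, function(p)
        length(intersect(unique(taxa[[kids[p[1L]]]]),
                         unique(taxa[[kids[p[2L]]]]))))
      cmb[, which.max(ov)]
    }
    cL <- kids[pairIdx[1L]]; cR <- kids[pairIdx[2L]]
    sL <- unique(taxa[[cL]]); sR <- unique(taxa[[cR]])
    shared <- intersect(sL, sR)
    if (length(shared) < minShared) next
    supPass <- function(s, thr) is.na(s) || s >= thr
    if (!supPass(gt$support[v], bp)) next
    if (!supPass(gt$support[cL], subBp) || !supPass(gt$support[cR], subBp))
      next
    spNode <- lcaMap(union(sL, sR), prep)
    rows[[length(rows) + 1L]] <- data.frame(
      family = family, node = v, species_node = spNode,
      species_label = speciesNodeLabel(spNode, prep),
      support = gt$support[v],
      childL_taxa = paste(sort(sL), collapse = ","),
      childR_taxa = paste(sort(sR), collapse = ","),
      childL_support = gt$support[cL], childR_support = gt$support[cR],
      stringsAsFactors = FALSE)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), node = integer(),
               species_node = integer(), species_label = character(),
               support = numeric(), childL_taxa = character(),
               childR_taxa = character(), childL_support = numeric(),
               childR_support = numeric(), stringsAsFactors = FALSE)
  new("GDEventSet", events = ev, speciesTree = prep$tree,
      params = list(bp = bp, subBp = subBp, minShared = minShared))
}

#' Detect duplications across a set of gene-family trees
#'
#' Roots each family tree against the species tree ([rootGeneTree()]) and
#' runs [detectDuplications()], pooling events into one [GDEventSet-class].
#'
#' @param trees named list of \code{"gtree"} objects (names are family
#'   ids) or a directory of Newick files.
#' @param speciesTree rooted species tree.
#' @param reroot root each gene tree by min duplications+losses first
#'   (default TRUE; set FALSE when trees are already reliably rooted).
#' @inheritParams detectDuplications
#' @param delim leaf-label delimiter used when \code{trees} is a directory.
#' @export
detectDuplicationsSet <- function(trees, speciesTree, bp = 70, subBp = 70,
                                  minShared = 2, reroot = TRUE,
                                  delim = "|") {
  prep <- prepSpeciesTree(speciesTree)
  if (is.character(trees) && length(trees) == 1L && dir.exists(trees)) {
    paths <- sort(list.files(trees, pattern = "\\.(nwk|newick|tre|tree)(\\.gz)?$",
                             full.names = TRUE))
    trees <- lapply(paths, readTree, delim = delim)
    names(trees) <- sub("\\.(nwk|newick|tre|tree)(\\.gz)?$", "",
                        basename(paths))
  }
  all <- list()
  for (fam in names(trees)) {
    gt <- trees[[fam]]
    if (reroot) gt <- rootGeneTree(gt, prep)
    ev <- detectDuplications(gt, prep, bp = bp, subBp = subBp,
                             minShared = minShared, family = fam)
    if (nrow(ev@events)) all[[fam]] <- ev@events
  }
  ev <- if (length(all)) do.call(rbind, all) else
    data.frame(family = character(), node = integer(),
               species_node = integer(), species_label = character(),
               support = numeric(), childL_taxa = character(),
               childR_taxa = character(), childL_support = numeric(),
               childR_support = numeric(), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  new("GDEventSet", events = ev, speciesTree = prep$tree,
      params = list(bp = bp, subBp = subBp, minShared = minShared))
}

#' Count duplication events per species-tree node
#'
#' @param events a [GDEventSet-class].
#' @return data.frame with species_node, species_label, n_events, sorted
#'   by node id; counts sum to \code{length(events)}.
#' @export
summarizeGD <- function(events) {
  stopifnot(is(events, "GDEventSet"))
  ev <- events@events
  prep <- prepSpeciesTree(events@speciesTree)
  nodes <- seq_len(prep$g$nNode)
  cnt <- integer(length(nodes))
  if (nrow(ev)) {
    tab <- table(ev$species_node)
    cnt[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(species_node = nodes,
             species_label = vapply(nodes, speciesNodeLabel, "", prep = prep),
             n_events = cnt, stringsAsFactors = FALSE)
}
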