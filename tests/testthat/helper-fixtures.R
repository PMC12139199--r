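# Shared fixtures: a rice-like species tree with two subspecies lineages
# of two genomes each, an aus genome and an outgroup.

riceSpeciesTree <- function() {
  ape::read.tree(text = "((((ind1,ind2),(jap1,jap2)),aus1),out);")
}

# focal node = MRCA of the indica+japonica lineages
riceFocalNode <- function(st = riceSpeciesTree()) {
  riceshift::lcaMap(c("ind1", "jap1"), st)
}

fourTaxonSpeciesTree <- function() {
  ape::read.tree(text = "(((A,B),C),D);")
}

# All rooted binary leaf-labeled tree shapes on leaf ids 1..n, as nested
# lists of leaf indices.
enumRootedShapes <- function(n) {
  rec <- function(ids) {
    if (length(ids) == 1L) return(list(ids))
    out <- list()
    first <- ids[1L]
    rest <- ids[-1L]
    # unordered splits: first leaf always on the left side
    for (mask in 0:(2^length(rest) - 1L)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_along(rest) - 1L)))
      left <- c(first, rest[sel])
      right <- rest[!sel]
      if (!length(right)) next
      for (lt in rec(left)) for (rt in rec(right))
        out[[length(out) + 1L]] <- list(lt, rt)
    }
    out
  }
  rec(seq_len(n))
}

# nested shape + taxon assignment -> newick with taxon|g<i> leaves
shapeToNewick <- function(shape, taxa) {
  rec <- function(nd) {
    if (!is.list(nd)) return(paste0(taxa[nd], "|g", nd))
    paste0("(", paste(vapply(nd, rec, ""), collapse = ","), ")")
  }
  paste0(rec(shape), ";")
}

# a random gene-tree newick over the given taxa (leaves taxon|g<i>)
randomGeneTreeNewick <- function(nLeaves, taxa) {
  shape <- sampleShape(nLeaves)
  assign <- sample(taxa, nLeaves, replace = TRUE)
  shapeToNewick(shape, assign)
}

# random rooted binary shape by random pairwise merging
sampleShape <- function(n) {
  items <- as.list(seq_len(n))
  while (length(items) > 1L) {
    i <- sample.int(length(items), 2L)
    merged <- list(items[[i[1L]]], items[[i[2L]]])
    items <- c(items[-i], list(merged))
  }
  items[[1L]]
}
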