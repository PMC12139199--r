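# ABAB/ABAX/ABXB typing of duplication events at a focal ancestral node.
# ABAB (both duplicate copies retain descendants of both lineages A and B)
# argues for independent divergence of A and B below the focal ancestor;
# ABAX/ABXB (one copy missing B resp. A) are the patterns a hybrid origin
# or differential loss would enrich.

#' Classify one duplication event's topology at a focal node
#'
#' Let A and B be the taxon sets of the two child lineages of the focal
#' species-tree node. The two duplicate-copy species sets are intersected
#' with A union B; extraneous lineages are ignored. The event is ABAB when
#' both copies contain at least one taxon of A and one of B; ABAX when one
#' copy contains both while the other contains only A; ABXB when the other
#' contains only B; OTHER otherwise (degenerate, e.g. a copy with no taxa
#' from A or B).
#'
#' @param childL,childR character vectors: taxa under the two duplicate
#'   copies (or comma-separated strings as stored in a
#'   [GDEventSet-class]).
#' @param A,B character vectors: the focal node's two descendant lineage
#'   taxon sets (disjoint, nonempty).
#' @return one of "ABAB", "ABAX", "ABXB", "OTHER".
#' @export
classifyTopology <- function(childL, childR, A, B) {
  if (!length(A) || !length(B)) stop("A and B must be nonempty", call. = FALSE)
  if (length(intersect(A, B))) stop("A and B must be disjoint", call. = FALSE)
  asSet <- function(x) {
    if (length(x) == 1L && grepl(",", x))
      x <- strsplit(x, ",", fixed = TRUE)[[1L]]
    unique(x)
  }
  sL <- intersect(asSet(childL), union(A, B))
  sR <- intersect(asSet(childR), union(A, B))
  if (!length(sL) || !length(sR)) return("OTHER")
  hasA <- function(s) any(s %in% A)
  hasB <- function(s) any(s %in% B)
  full <- function(s) hasA(s) && hasB(s)
  if (full(sL) && full(sR)) return("ABAB")
  if (full(sL) || full(sR)) {
    other <- if (full(sL)) sR else sL
    if (hasA(other) && !hasB(other)) return("ABAX")
    if (hasB(other) && !hasA(other)) return("ABXB")
  }
  "OTHER"
}

#' Type all events of a GDEventSet at a focal species-tree node
#'
#' @param events a [GDEventSet-class].
#' @param focalNode species-tree node id the events must be placed at;
#'   events at other nodes raise an error unless \code{strict = FALSE}
#'   (then they are dropped).
#' @param A,B the focal node's two descendant lineage taxon sets. When
#'   omitted they are taken from the species tree as the taxa below the
#'   focal node's two children.
#' @param strict error on events not placed at the focal node.
#' @return the events data.frame with an added \code{topology} column.
#' @export
classifyTopologySet <- function(events, focalNode, A = NULL, B = NULL,
                                strict = TRUE) {
  stopifnot(is(events, "GDEventSet"))
  ev <- events@events
  prep <- prepSpeciesTree(events@speciesTree)
  if (is.null(A) || is.null(B)) {
    kids <- prep$g$children[[focalNode]]
    if (length(kids) != 2L)
      stop("focal node is not binary; supply A and B explicitly",
           call. = FALSE)
    A <- prep$leafSets[[kids[1L]]]
    B <- prep$leafSets[[kids[2L]]]
  }
  off <- ev$species_node != focalNode
  if (any(off)) {
    if (strict)
      stop(sum(off), " event(s) not placed at the focal node", call. = FALSE)
    ev <- ev[!off, , drop = FALSE]
  }
  ev$topology <- vapply(seq_len(nrow(ev)), function(i)
    classifyTopology(ev$childL_taxa[i], ev$childR_taxa[i], A, B),
    character(1))
  ev
}

#' Tabulate topology-class proportions
#'
#' @param topology character vector of classes (from
#'   [classifyTopologySet()]) or a data.frame with a \code{topology}
#'   column.
#' @return data.frame with class, n, proportion; proportions sum to 1.
#' @export
tabulateTopologies <- function(topology) {
  if (is.data.frame(topology)) topology <- topology$topology
  if (!length(topology)) stop("no events to tabulate", call. = FALSE)
  lev <- c("ABAB", "ABAX", "ABXB", "OTHER")
  tab <- table(factor(topology, levels = lev))
  out <- data.frame(class = lev, n = as.integer(tab),
                    proportion = as.numeric(tab) / length(topology),
                    stringsAsFactors = FALSE)
  out[out$n > 0 | out$class != "OTHER", , drop = FALSE]
}
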