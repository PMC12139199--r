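#' @import methods
NULL

#' Gene-duplication event set
#'
#' Container for duplication events detected across one or more gene
#' families against a common rooted species tree. One row of
#' \code{events} per event: the gene-family id, the gene-tree node, the
#' species-tree node the event reconciles to (and a human-readable label),
#' the bipartition supports involved, and the taxa under the two duplicate
#' copies.
#'
#' @slot events data.frame with columns family, node, species_node,
#'   species_label, support, childL_taxa, childR_taxa, childL_support,
#'   childR_support.
#' @slot speciesTree the rooted species tree (\code{ape::phylo}).
#' @slot params list of detection thresholds (bp, subBp, minShared).
#' @export
setClass("GDEventSet",
         representation(events = "data.frame", speciesTree = "ANY",
                        params = "list"),
         prototype(events = data.frame(), params = list()))

setValidity("GDEventSet", function(object) {
  need <- c("family", "node", "species_node", "species_label", "support",
            "childL_taxa", "childR_taxa", "childL_support", "childR_support")
  if (nrow(object@events) > 0 && !all(need %in% names(object@events)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (!is.null(object@speciesTree) && !inherits(object@speciesTree, "phylo"))
    return("speciesTree must be an ape phylo object")
  TRUE
})

#' @describeIn GDEventSet number of events
#' @param x a GDEventSet
#' @export
setMethod("length", "GDEventSet", function(x) nrow(x@events))

setMethod("show", "GDEventSet", function(object) {
  cat("GDEventSet with", nrow(object@events), "duplication event(s)\n")
  if (length(object@params))
    cat("  thresholds: bp=", object@params$bp, " sub_bp=", object@params$subBp,
        " min shared species=", object@params$minShared, "\n", sep = "")
  if (nrow(object@events)) {
    tab <- table(object@events$species_label)
    cat("  events per species-tree node:\n")
    for (nm in names(tab)) cat("    ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
})

#' Accessor: the per-event table of a GDEventSet
#' @param x a \code{GDEventSet}
#' @return data.frame of events
#' @export
gdEvents <- function(x) {
  stopifnot(is(x, "GDEventSet"))
  x@events
}

#' Nei-Gojobori pairwise Ka/Ks result
#'
#' Site counts, pathway-averaged difference counts, and Jukes-Cantor
#' corrected distances for one codon-aligned sequence pair. \code{Ks}
#' (resp. \code{Ka}) is \code{NA} when the synonymous (nonsynonymous)
#' difference proportion reaches the 3/4 saturation bound; \code{KaKs} is
#' \code{NA} when \code{Ks} is 0 or undefined.
#'
#' @slot S,N synonymous / nonsynonymous site counts (fractional).
#' @slot Sd,Nd pathway-averaged difference counts.
#' @slot pS,pN difference proportions.
#' @slot Ka,Ks Jukes-Cantor corrected distances (NA when saturated).
#' @slot KaKs the ratio (NA when undefined).
#' @slot nCodons number of retained codon columns.
#' @slot status "ok", "saturated_ks", "saturated_ka" or "saturated_both".
#' @export
setClass("KsResult",
         representation(S = "numeric", N = "numeric", Sd = "numeric",
                        Nd = "numeric", pS = "numeric", pN = "numeric",
                        Ka = "numeric", Ks = "numeric", KaKs = "numeric",
                        nCodons = "integer", status = "character"))

setValidity("KsResult", function(object) {
  if (abs(object@S + object@N - 3 * object@nCodons) > 1e-6)
    return("S + N must equal 3 x retained codons")
  if (object@S > 0 && !is.na(object@pS) &&
      abs(object@pS - object@Sd / object@S) > 1e-9)
    return("pS must equal Sd/S")
  TRUE
})

setMethod("show", "KsResult", function(object) {
  cat(sprintf("KsResult (%d codons): S=%.2f N=%.2f Sd=%.3f Nd=%.3f\n",
              object@nCodons, object@S, object@N, object@Sd, object@Nd))
  cat(sprintf("  Ka=%s Ks=%s Ka/Ks=%s [%s]\n",
              fmtNA(object@Ka), fmtNA(object@Ks), fmtNA(object@KaKs),
              object@status))
})

fmtNA <- function(x) if (is.na(x)) "NA" else sprintf("%.5f", x)

#' Classified trio variant sites
#'
#' Per-site inheritance classification of F1/parent genotypes plus filter
#' status. Sites with any missing genotype are \code{unclassified}.
#'
#' @slot sites data.frame with at least chrom, pos, gt_f1, gt_p1, gt_p2,
#'   class, mendelian_consistent.
#' @export
setClass("TrioCalls", representation(sites = "data.frame"))

setValidity("TrioCalls", function(object) {
  need <- c("gt_f1", "gt_p1", "gt_p2", "class")
  if (nrow(object@sites) > 0 && !all(need %in% names(object@sites)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  ok <- c("inherited_P1", "inherited_P2", "shared", "de_novo", "unclassified")
  if (nrow(object@sites) > 0 && !all(object@sites$class %in% ok))
    return("unknown inheritance class label")
  TRUE
})

setMethod("show", "TrioCalls", function(object) {
  cat("TrioCalls with", nrow(object@sites), "site(s)\n")
  if (nrow(object@sites)) {
    tab <- table(object@sites$class)
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
})

#' Accessor: per-site table of a TrioCalls object
#' @param x a \code{TrioCalls}
#' @export
trioSites <- function(x) {
  stopifnot(is(x, "TrioCalls"))
  x@sites
}

#' Heterosis expression-mode calls
#'
#' Per-gene seven-way inheritance-mode classification of F1 expression
#' relative to the parents (A, PD, ND, PPD, NPD, POD, NOD; NC when the
#' significance pattern is not classifiable; low_expression genes are
#' excluded before testing).
#'
#' @slot calls data.frame with gene_id, meanP1, meanP2, meanF1, callHP,
#'   callLP, callMP, mode.
#' @slot alpha significance level used for the Welch tests.
#' @export
setClass("HeterosisModes",
         representation(calls = "data.frame", alpha = "numeric"))

setValidity("HeterosisModes", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be a single value in (0,1)")
  TRUE
})

setMethod("show", "HeterosisModes", function(object) {
  cat("HeterosisModes:", nrow(object@calls), "gene(s), alpha =",
      object@alpha, "\n")
  if (nrow(object@calls)) {
    tab <- table(object@calls$mode)
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
})

#' Accessor: per-gene mode calls
#' @param x a \code{HeterosisModes}
#' @export
modeCalls <- function(x) {
  stopifnot(is(x, "HeterosisModes"))
  x@calls
}
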