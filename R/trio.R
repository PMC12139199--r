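# Variant hard filtering, depth-band filtering and trio inheritance
# classification.

#' GATK-style hard filter for SNP sites
#'
#' A site fails when ANY of: QD < 10, FS > 60, MQ < 40, SOR > 3,
#' MQRankSum < -12.5, ReadPosRankSum < -8. Absent (NA) fields never
#' trigger a failure.
#'
#' @param sites data.frame with any of the columns QD, FS, MQ, SOR,
#'   MQRankSum, ReadPosRankSum (e.g. from [readTrioVcf()]).
#' @return list with \code{pass} (logical vector) and \code{reasons}
#'   (list of character vectors naming every violated predicate).
#' @export
hardFilter <- function(sites) {
  preds <- list(
    QD = function(x) x < 10.0,
    FS = function(x) x > 60.0,
    MQ = function(x) x < 40.0,
    SOR = function(x) x > 3.0,
    MQRankSum = function(x) x < -12.5,
    ReadPosRankSum = function(x) x < -8.0)
  n <- nrow(sites)
  reasons <- vector("list", n)
  for (i in seq_len(n)) reasons[[i]] <- character(0)
  for (key in names(preds)) {
    if (!key %in% names(sites)) next
    bad <- preds[[key]](sites[[key]])
    bad[is.na(bad)] <- FALSE
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], key)
  }
  list(pass = lengths(reasons) == 0L, reasons = reasons)
}

#' Depth-band filter
#'
#' A sample's depth fails when it is below one-third or above three times
#' the sample's mean depth (strict inequalities: boundary depths pass).
#' With a depth matrix, a site fails when any trio member fails.
#'
#' @param depths numeric vector, or matrix with one column per sample.
#' @param meanDepth per-sample mean depth (recycled across columns).
#' @return logical pass vector (one per site).
#' @export
depthFilter <- function(depths, meanDepth) {
  stopifnot(all(meanDepth > 0))
  if (is.null(dim(depths))) depths <- matrix(depths, ncol = 1L)
  meanDepth <- rep_len(meanDepth, ncol(depths))
  ok <- matrix(TRUE, nrow(depths), ncol(depths))
  for (j in seq_len(ncol(depths))) {
    d <- depths[, j]
    ok[, j] <- !(d < meanDepth[j] / 3 | d > 3 * meanDepth[j])
    ok[is.na(d), j] <- FALSE
  }
  rowSums(!ok) == 0L
}

#' Classify trio sites by full-genotype matching
#'
#' The F1 genotype is compared with each parent's genotype as an
#' unordered allele multiset. Matching both parents = \code{shared};
#' exactly one = \code{inherited_P1}/\code{inherited_P2}; neither =
#' \code{de_novo}; any missing genotype = \code{unclassified}. This is
#' deliberately full-genotype matching, not Mendelian-transmission
#' consistency: a het F1 from hom-ref x hom-alt parents is \code{de_novo}
#' under this rule even though it is Mendelian-consistent (reported in the
#' \code{mendelian_consistent} flag of [classifyTrio()]).
#'
#' @param f1,p1,p2 character vectors of normalized genotypes (see
#'   [normalizeGenotype()]); NA = missing.
#' @return character vector of classes.
#' @export
classifyTrioSite <- function(f1, p1, p2) {
  m1 <- !is.na(f1) & !is.na(p1) & f1 == p1
  m2 <- !is.na(f1) & !is.na(p2) & f1 == p2
  out <- rep("unclassified", length(f1))
  full <- !is.na(f1) & !is.na(p1) & !is.na(p2)
  out[full & m1 & m2] <- "shared"
  out[full & m1 & !m2] <- "inherited_P1"
  out[full & !m1 & m2] <- "inherited_P2"
  out[full & !m1 & !m2] <- "de_novo"
  out
}

mendelianConsistent <- function(f1, p1, p2) {
  vapply(seq_along(f1), function(i) {
    if (is.na(f1[i]) || is.na(p1[i]) || is.na(p2[i])) return(NA)
    a <- strsplit(f1[i], "/", fixed = TRUE)[[1L]]
    g1 <- strsplit(p1[i], "/", fixed = TRUE)[[1L]]
    g2 <- strsplit(p2[i], "/", fixed = TRUE)[[1L]]
    (a[1L] %in% g1 && a[2L] %in% g2) || (a[2L] %in% g1 && a[1L] %in% g2)
  }, logical(1))
}

#' Classify a trio site table
#'
#' Applies [classifyTrioSite()] to a table from [readTrioVcf()] or
#' [simulateTrio()], adding the class and a Mendelian-consistency flag.
#'
#' @param sites data.frame with gt_f1, gt_p1, gt_p2 columns.
#' @return a [TrioCalls-class].
#' @export
classifyTrio <- function(sites) {
  sites$class <- classifyTrioSite(sites$gt_f1, sites$gt_p1, sites$gt_p2)
  sites$mendelian_consistent <-
    mendelianConsistent(sites$gt_f1, sites$gt_p1, sites$gt_p2)
  new("TrioCalls", sites = sites)
}

#' Allele-frequency spectrum
#'
#' Right-closed binning of per-site allele frequencies, plus the fraction
#' of sites with AF > 0.9.
#'
#' @param af numeric vector of allele frequencies in \eqn{[0,1]}.
#' @param binEdges bin boundaries (default deciles).
#' @return list with \code{counts} (named per bin), \code{n},
#'   \code{fractionAbove0.9}.
#' @export
afSpectrum <- function(af, binEdges = seq(0, 1, by = 0.1)) {
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequency outside [0, 1]", call. = FALSE)
  af <- af[!is.na(af)]
  counts <- if (length(af))
    table(cut(af, breaks = binEdges, include.lowest = TRUE, right = TRUE))
  else {
    z <- table(cut(numeric(0), breaks = binEdges, include.lowest = TRUE))
    z
  }
  list(counts = counts, n = length(af),
       fractionAbove0.9 = if (length(af)) mean(af > 0.9) else NA_real_)
}

#' Nonsynonymous/synonymous (M/S) count ratio
#'
#' @param effect character vector of per-site annotation effect classes;
#'   \code{missense} and \code{nonsense} count as nonsynonymous,
#'   \code{synonymous} as synonymous; other labels are counted separately
#'   and ignored by the ratio.
#' @return list with nNonsyn, nSyn, nOther, ratio (NA when nSyn = 0).
#' @export
msRatio <- function(effect) {
  nonsyn <- sum(effect %in% c("missense", "nonsense", "missense_variant",
                              "stop_gained", "stop_lost"))
  syn <- sum(effect %in% c("synonymous", "synonymous_variant"))
  other <- length(effect) - nonsyn - syn
  list(nNonsyn = nonsyn, nSyn = syn, nOther = other,
       ratio = if (syn > 0) nonsyn / syn else NA_real_)
}

#' Genotype composition of classified trio sites
#'
#' Proportions of inherited_P1 / inherited_P2 / shared / de_novo among
#' classified (non-missing) sites.
#'
#' @param x a [TrioCalls-class] or a character vector of classes.
#' @return data.frame with class, n, proportion (sums to 1 over
#'   classified sites).
#' @export
genotypeComposition <- function(x) {
  cls <- if (is(x, "TrioCalls")) x@sites$class else x
  cls <- cls[cls != "unclassified"]
  if (!length(cls)) stop("no classified sites", call. = FALSE)
  lev <- c("inherited_P1", "inherited_P2", "shared", "de_novo")
  tab <- table(factor(cls, levels = lev))
  data.frame(class = lev, n = as.integer(tab),
             proportion = as.integer(tab) / length(cls),
             stringsAsFactors = FALSE)
}
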