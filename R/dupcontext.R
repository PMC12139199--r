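# Tandem-duplication calling by gene-order proximity and TE-proximity
# association testing.

#' Call tandem duplications from gene-order proximity
#'
#' Two duplicated genes form a tandem pair when they lie on the same
#' chromosome with at most \code{maxIntervening} annotated genes between
#' them (intervening count = |ordinal difference| - 1, over all annotated
#' genes on the chromosome).
#'
#' @param pairs data.frame with columns \code{gene1}, \code{gene2}.
#' @param geneOrder data.frame from [readGeneOrder()] (gene_id, chrom,
#'   ordinal).
#' @param maxIntervening maximum intervening genes permitted (default 10).
#' @return data.frame: gene1, gene2, same_chrom, intervening (NA across
#'   chromosomes), is_tandem.
#' @export
findTandemPairs <- function(pairs, geneOrder, maxIntervening = 10) {
  idx <- match(c(pairs$gene1, pairs$gene2), geneOrder$gene_id)
  if (anyNA(idx)) {
    bad <- c(pairs$gene1, pairs$gene2)[is.na(idx)]
    stop("gene(s) not in gene order: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  i1 <- idx[seq_len(nrow(pairs))]
  i2 <- idx[nrow(pairs) + seq_len(nrow(pairs))]
  sameChrom <- geneOrder$chrom[i1] == geneOrder$chrom[i2]
  interv <- ifelse(sameChrom,
                   abs(geneOrder$ordinal[i1] - geneOrder$ordinal[i2]) - 1L,
                   NA_integer_)
  data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
             same_chrom = sameChrom, intervening = interv,
             is_tandem = sameChrom & !is.na(interv) &
               interv <= maxIntervening,
             stringsAsFactors = FALSE)
}

#' TE proximity of genes within a flanking window
#'
#' A gene is TE-associated when any transposable-element interval overlaps
#' the window \code{[start - window, end + window]} (clamped at 1) by at
#' least one base, all coordinates 1-based inclusive.
#'
#' @param genes data.frame with gene_id, chrom, start, end.
#' @param te data.frame of TE intervals with chrom, start, end.
#' @param window flank size in bp on each side (default 2000).
#' @return logical vector named by gene_id.
#' @export
teProximity <- function(genes, te, window = 2000) {
  gw <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(pmax(1L, genes$start - window),
                           genes$end + window))
  tr <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start, te$end))
  hits <- GenomicRanges::countOverlaps(gw, tr) > 0
  names(hits) <- genes$gene_id
  hits
}

#' Pearson chi-square test on a 2x2 table
#'
#' Statistic \eqn{n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with df = 1;
#' the Yates continuity correction is applied only when requested.
#'
#' @param a,b,c,d cell counts (dup&TE, dup&noTE, nondup&TE, nondup&noTE),
#'   or \code{a} may be a 2x2 matrix.
#' @param yates apply the continuity correction (default FALSE).
#' @return list with statistic, df, p.value.
#' @export
chiSquare2x2 <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers", call. = FALSE)
  n <- sum(cnt)
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0))
    stop("zero margin; use an exact test instead", call. = FALSE)
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(m)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' TE-association test for duplicated vs non-duplicated genes
#'
#' Builds the 2x2 table (duplicated/non-duplicated x TE-associated/not)
#' from [teProximity()] calls and runs [chiSquare2x2()].
#'
#' @param genes gene table (gene_id, chrom, start, end).
#' @param dupGenes character vector of duplicated gene ids.
#' @param te TE interval table.
#' @inheritParams teProximity
#' @inheritParams chiSquare2x2
#' @return list with \code{table} (2x2 matrix) and \code{test}.
#' @export
teAssociationTest <- function(genes, dupGenes, te, window = 2000,
                              yates = FALSE) {
  teFlag <- teProximity(genes, te, window = window)
  dup <- genes$gene_id %in% dupGenes
  tab <- matrix(c(sum(dup & teFlag), sum(dup & !teFlag),
                  sum(!dup & teFlag), sum(!dup & !teFlag)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("dup", "nondup"), c("TE", "noTE")))
  list(table = tab, test = chiSquare2x2(tab, yates = yates))
}
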