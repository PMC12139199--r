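#' Read a gene tree or species tree from Newick
#'
#' Leaf labels of gene trees are expected to encode the source genome and
#' the gene copy as \code{taxon<delim>gene} (default delimiter \code{"|"}).
#' Bootstrap supports are read from internal node labels on a 0--100 scale;
#' labels in \eqn{[0,1]} are rescaled by 100 with a warning; absent labels
#' are kept as missing (never coerced to 0).
#'
#' @param path path to a Newick file (plain or gzip-compressed), or a
#'   Newick string ending in \code{";"}.
#' @param delim delimiter separating taxon from gene in leaf labels; use
#'   \code{NA} for species trees whose leaves are bare taxon ids.
#' @return an object of internal class \code{"gtree"}: a rooted tree whose
#'   tips carry \code{taxon} and \code{gene} and whose nodes carry the
#'   support of the edge above them.
#' @examples
#' gt <- readTree("((A|g1,B|g2)95,C|g3);")
#' @export
readTree <- function(path, delim = "|") {
  txt <- readNewickText(path)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("Newick parse error in '", substr(txt, 1, 60), "...'", call. = FALSE)
  asGtree(phy, delim = delim)
}

readNewickText <- function(path) {
  if (!file.exists(path)) {
    if (grepl("[(),]", path)) return(path)  # inline Newick (possibly broken)
    stop("file not found: ", path, call. = FALSE)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  paste(readLines(con, warn = FALSE), collapse = "")
}

#' Write a tree back to Newick
#'
#' Round-trips topology, labels, branch lengths and supports losslessly.
#'
#' @param gt a \code{"gtree"} as returned by [readTree()].
#' @param path output file; when \code{NULL} the Newick string is returned.
#' @export
writeTree <- function(gt, path = NULL) {
  nwk <- gtreeToNewick(gt)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Read gene coordinates and assign chromosome ordinals
#'
#' Accepts GFF3 (\code{gene} features; \code{mRNA} used when no \code{gene}
#' rows exist) or a TSV with columns \code{gene_id, chrom, start, end}
#' and optional \code{strand}. Coordinates are 1-based inclusive. A dense
#' ordinal 1..n is assigned along each chromosome by start, ties broken by
#' end then gene_id; the ordinal is the gene-rank substrate for tandem
#' duplication calling.
#'
#' @param path GFF3 or TSV file (optionally gzipped).
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   ordinal.
#' @export
readGeneOrder <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    keep <- gr[gr$type == "gene"]
    if (length(keep) == 0L) keep <- gr[gr$type == "mRNA"]
    ids <- keep$ID
    if (is.null(ids)) ids <- keep$Name
    df <- data.frame(gene_id = as.character(ids),
                     chrom = as.character(GenomicRanges::seqnames(keep)),
                     start = GenomicRanges::start(keep),
                     end = GenomicRanges::end(keep),
                     strand = as.character(GenomicRanges::strand(keep)),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df)))
      stop("gene table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (is.null(df$strand)) df$strand <- "+"
  }
  assignOrdinals(df)
}

#' @rdname readGeneOrder
#' @param df data.frame with gene_id, chrom, start, end (1-based inclusive).
#' @export
assignOrdinals <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  if (any(df$start > df$end))
    stop("start > end for: ",
         paste(df$gene_id[df$start > df$end], collapse = ", "), call. = FALSE)
  if (any(df$start < 1)) stop("coordinates must be positive", call. = FALSE)
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  df$ordinal <- stats::ave(seq_len(nrow(df)), df$chrom,
                           FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Normalize a VCF genotype string
#'
#' Genotypes become unordered allele multisets: \code{"1/0"} and phased
#' \code{"0|1"} both normalize to \code{"0/1"}; any genotype containing a
#' missing allele normalizes to \code{NA}.
#'
#' @param gt character vector of GT strings.
#' @return character vector of sorted, slash-separated genotypes or NA.
#' @export
normalizeGenotype <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g == "" || g == ".") return(NA_character_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == "." | al == "")) return(NA_character_)
    paste(sort(as.integer(al)), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a parent/F1 trio from a VCF
#'
#' Extracts per-site genotypes (normalized to unordered multisets), sample
#' depths, and the hard-filter INFO annotations (QD, FS, MQ, SOR,
#' MQRankSum, ReadPosRankSum, DP) when present. Multiallelic sites are
#' decomposed per alternate allele; in the decomposed row for alternate
#' \eqn{k}, genotypes carrying a different alternate are set missing.
#'
#' @param path VCF v4.2 file, optionally gzipped.
#' @param f1,p1,p2 sample names of the offspring and the two parents.
#' @return data.frame with one row per (site, alt allele): chrom, pos,
#'   ref, alt, gt_f1, gt_p1, gt_p2, dp_f1, dp_p1, dp_p2, and the INFO
#'   columns (NA when absent).
#' @export
readTrioVcf <- function(path, f1, p1, p2) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1L]
  for (s in c(f1, p1, p2))
    if (!s %in% samples)
      stop("sample '", s, "' not in VCF header; samples are: ",
           paste(samples, collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  fix <- vcfR::getFIX(v)
  infoKeys <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum", "DP")
  info <- sapply(infoKeys, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = k))))
  if (is.null(dim(info))) info <- matrix(info, nrow = 1,
                                         dimnames = list(NULL, infoKeys))
  out <- list()
  for (i in seq_len(nrow(gt))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (k in seq_along(alts)) {
      g3 <- c(gt[i, f1], gt[i, p1], gt[i, p2])
      if (length(alts) > 1L) g3 <- recodeForAlt(g3, k)
      g3 <- normalizeGenotype(g3)
      row <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gt_f1 = g3[1L], gt_p1 = g3[2L], gt_p2 = g3[3L],
        dp_f1 = dp[i, f1], dp_p1 = dp[i, p1], dp_p2 = dp[i, p2],
        stringsAsFactors = FALSE)
      for (ik in infoKeys) row[[ik]] <- unname(info[i, ik])
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# For multiallelic decomposition: keep alleles 0 and k (k -> 1); a
# genotype containing any other alternate becomes missing for this row.
recodeForAlt <- function(gts, k) {
  vapply(gts, function(g) {
    if (is.na(g) || g == "." || g == "") return(NA_character_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == "." | al == "")) return(NA_character_)
    ai <- as.integer(al)
    if (any(!ai %in% c(0L, k))) return(NA_character_)
    paste(ifelse(ai == k, 1L, 0L), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}
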