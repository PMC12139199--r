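# Nei-Gojobori (1986) Ka/Ks engine with Jukes-Cantor correction.

BASES <- c("A", "C", "G", "T")

# codon -> amino acid, standard code; "*" for stops
codonAA <- function(codon, code = NULL) {
  if (is.null(code)) code <- Biostrings::GENETIC_CODE
  unname(code[codon])
}

senseCodons <- function(code = NULL) {
  if (is.null(code)) code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

# memoized per-codon synonymous site counts for the standard code
.siteCountCache <- new.env(parent = emptyenv())

#' Synonymous/nonsynonymous site counts of a codon
#'
#' For each of the three positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous is accumulated; changes
#' creating a stop codon count as nonsynonymous. Returns \code{c(s, n)}
#' with \code{s + n = 3}.
#'
#' @param codon a 3-letter sense codon (standard genetic code).
#' @param code optional named genetic-code vector (codon -> amino acid,
#'   \code{"*"} for stop); defaults to the standard code.
#' @return numeric vector \code{c(s = , n = )}.
#' @export
codonSiteCounts <- function(codon, code = NULL) {
  std <- is.null(code)
  if (std && !is.null(.siteCountCache[[codon]]))
    return(.siteCountCache[[codon]])
  if (is.null(code)) code <- Biostrings::GENETIC_CODE
  if (!codon %in% names(code) || code[[codon]] == "*")
    stop("not a sense codon: ", codon, call. = FALSE)
  aa <- code[[codon]]
  s <- 0
  nt <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    for (b in setdiff(BASES, nt[pos])) {
      mut <- nt; mut[pos] <- b
      mcod <- paste(mut, collapse = "")
      if (code[[mcod]] != "*" && code[[mcod]] == aa) s <- s + 1 / 3
    }
  }
  out <- c(s = s, n = 3 - s)
  if (std) .siteCountCache[[codon]] <- out
  out
}

# All orderings of k positions, k in 1..3.
.permList <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Pathway-averaged (Sd, Nd) contribution of one differing codon pair.
# Pathways passing through a stop codon are excluded; if every pathway
# does, all are used (stop steps then count as nonsynonymous).
codonPairDiffs <- function(c1, c2, code) {
  nt1 <- strsplit(c1, "")[[1L]]
  nt2 <- strsplit(c2, "")[[1L]]
  diffPos <- which(nt1 != nt2)
  k <- length(diffPos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- .permList[[k]]
  contrib <- matrix(NA_real_, nrow = length(paths), ncol = 2L)
  valid <- logical(length(paths))
  for (p in seq_along(paths)) {
    cur <- nt1
    sd <- nd <- 0
    hitStop <- FALSE
    for (step in paths[[p]]) {
      pos <- diffPos[step]
      prev <- paste(cur, collapse = "")
      cur[pos] <- nt2[pos]
      nxt <- paste(cur, collapse = "")
      aaPrev <- code[[prev]]; aaNxt <- code[[nxt]]
      if (aaNxt == "*" && nxt != c2) hitStop <- TRUE
      if (aaPrev == aaNxt && aaPrev != "*") sd <- sd + 1 else nd <- nd + 1
    }
    contrib[p, ] <- c(sd, nd)
    valid[p] <- !hitStop
  }
  use <- if (any(valid)) valid else rep(TRUE, length(paths))
  c(sd = mean(contrib[use, 1L]), nd = mean(contrib[use, 2L]))
}

#' Jukes-Cantor correction of a difference proportion
#'
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4p}{3})}. Saturated proportions
#' (\eqn{p \ge 3/4}) return \code{NA} (undefined distance), not an error.
#'
#' @param p difference proportion(s) in \eqn{[0, 1]}.
#' @return corrected distance(s); \code{NA} where saturated.
#' @export
jcCorrect <- function(p) {
  if (any(p < 0, na.rm = TRUE))
    stop("proportion must be nonnegative", call. = FALSE)
  ifelse(is.na(p) | p >= 0.75, NA_real_,
         ifelse(p == 0, 0, -0.75 * log(1 - 4 * p / 3)))
}

#' Nei-Gojobori Ka/Ks for one codon-aligned pair
#'
#' Codon columns containing gaps, ambiguous bases or stop codons in
#' either sequence are excluded from all counts. Synonymous (S) and
#' nonsynonymous (N) site totals are the mean of the two sequences' sums;
#' difference counts are averaged over all orderings of single-nucleotide
#' steps between differing codons, excluding pathways through stop codons
#' (unweighted mean, as in the original method). pS and pN are corrected
#' with the Jukes-Cantor formula.
#'
#' @param x,y aligned coding sequences (character strings or
#'   \code{Biostrings::DNAString}); equal length, a multiple of 3.
#' @param code optional genetic code (defaults to the standard code).
#' @return a [KsResult-class].
#' @export
ng86Pair <- function(x, y, code = NULL) {
  x <- toupper(as.character(x)); y <- toupper(as.character(y))
  if (nchar(x) != nchar(y))
    stop("sequences must have equal length", call. = FALSE)
  if (nchar(x) %% 3 != 0)
    stop("alignment length must be a multiple of 3", call. = FALSE)
  if (is.null(code)) code <- Biostrings::GENETIC_CODE
  nCod <- nchar(x) / 3
  cods1 <- substring(x, 3 * seq_len(nCod) - 2, 3 * seq_len(nCod))
  cods2 <- substring(y, 3 * seq_len(nCod) - 2, 3 * seq_len(nCod))
  clean <- function(cs) cs %in% names(code) & code[cs] != "*" &
    grepl("^[ACGT]{3}$", cs)
  keep <- clean(cods1) & clean(cods2)
  if (!any(keep)) stop("no retained codon columns", call. = FALSE)
  cods1 <- cods1[keep]; cods2 <- cods2[keep]

  sc1 <- vapply(cods1, codonSiteCounts, numeric(2), code = code)
  sc2 <- vapply(cods2, codonSiteCounts, numeric(2), code = code)
  S <- (sum(sc1["s", ]) + sum(sc2["s", ])) / 2
  N <- (sum(sc1["n", ]) + sum(sc2["n", ])) / 2

  Sd <- Nd <- 0
  for (i in which(cods1 != cods2)) {
    d <- codonPairDiffs(cods1[i], cods2[i], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jcCorrect(pS)
  Ka <- jcCorrect(pN)
  status <- if (is.na(Ks) && is.na(Ka)) "saturated_both"
            else if (is.na(Ks)) "saturated_ks"
            else if (is.na(Ka)) "saturated_ka"
            else "ok"
  KaKs <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  new("KsResult", S = S, N = N, Sd = Sd, Nd = Nd,
      pS = pS, pN = pN, Ka = Ka, Ks = Ks, KaKs = KaKs,
      nCodons = sum(keep), status = status)
}

#' Ka/Ks for a list of aligned pairs
#'
#' @param pairs named list; each element a list/character vector of two
#'   aligned sequences.
#' @inheritParams ng86Pair
#' @return data.frame with pair_id, S, N, Sd, Nd, pS, pN, Ka, Ks, KaKs,
#'   n_codons_retained, status.
#' @export
ng86Table <- function(pairs, code = NULL) {
  rows <- lapply(names(pairs), function(id) {
    r <- ng86Pair(pairs[[id]][[1L]], pairs[[id]][[2L]], code = code)
    data.frame(pair_id = id, S = r@S, N = r@N, Sd = r@Sd, Nd = r@Nd,
               pS = r@pS, pN = r@pN, Ka = r@Ka, Ks = r@Ks, KaKs = r@KaKs,
               n_codons_retained = r@nCodons, status = r@status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ks density summary and modal Ks
#'
#' Gaussian kernel density over the finite Ks values on a 512-point grid
#' from 0 to the maximum; saturated/undefined values are excluded and
#' counted. Reports the global mode and all local maxima of the grid.
#'
#' @param ks numeric vector of Ks values (NA = saturated/undefined).
#' @param bw kernel bandwidth passed to [stats::density()].
#' @return list with \code{density} (a \code{stats::density} object or
#'   NULL for a degenerate constant sample), \code{mode}, \code{localModes},
#'   \code{nUsed}, \code{nExcluded}.
#' @export
ksDistribution <- function(ks, bw = "nrd0") {
  finite <- ks[is.finite(ks)]
  nEx <- length(ks) - length(finite)
  if (length(finite) < 2L)
    stop("need at least 2 finite Ks values", call. = FALSE)
  if (stats::sd(finite) == 0)
    return(list(density = NULL, mode = finite[1L], localModes = finite[1L],
                nUsed = length(finite), nExcluded = nEx))
  d <- stats::density(finite, bw = bw, n = 512, from = 0, to = max(finite))
  i <- which.max(d$y)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(loc)) loc <- i
  list(density = d, mode = d$x[i], localModes = d$x[loc],
       nUsed = length(finite), nExcluded = nEx)
}

#' Molecular-clock gene selection by CDS length and taxa coverage
#'
#' Retains genes with \code{minLen <= length_bp <= maxLen} (boundaries
#' inclusive) and taxa coverage at least \code{minCoverage}.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{length_bp}
#'   and optionally \code{coverage} (fraction of taxa represented).
#' @param minLen,maxLen inclusive length window in bp (defaults 900 and
#'   1200).
#' @param minCoverage minimum taxa coverage (default 0 = no constraint).
#' @return the filtered data.frame (possibly empty, with a message).
#' @export
selectClockGenes <- function(genes, minLen = 900, maxLen = 1200,
                             minCoverage = 0) {
  keep <- genes$length_bp >= minLen & genes$length_bp <= maxLen
  if (minCoverage > 0 && !is.null(genes$coverage))
    keep <- keep & genes$coverage >= minCoverage
  out <- genes[keep, , drop = FALSE]
  if (!nrow(out)) message("no genes pass the clock-gene filter")
  rownames(out) <- NULL
  out
}
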