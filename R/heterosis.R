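# Seven-way F1-vs-parents expression-mode classification (heterosis
# inheritance modes) and the DE-retention prefilter.

#' Directional significance call between two replicate groups
#'
#' Welch two-sided t-test on log2(TPM + 1); significant at \code{alpha},
#' direction from the sign of the mean difference (group1 minus group2).
#' When both groups are essentially constant, equal means give \code{ns}
#' and unequal means give a significant call in the direction of the
#' difference.
#'
#' @param g1,g2 numeric replicate vectors (TPM, >= 2 each).
#' @param alpha significance level (default 0.05).
#' @return one of "sig_higher", "sig_lower", "ns".
#' @export
sigCall <- function(g1, g2, alpha = 0.05) {
  if (length(g1) < 2L || length(g2) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  l1 <- log2(g1 + 1); l2 <- log2(g2 + 1)
  d <- mean(l1) - mean(l2)
  eps <- 1e-12
  if (stats::sd(l1) < eps && stats::sd(l2) < eps) {
    if (abs(d) < eps) return("ns")
    return(if (d > 0) "sig_higher" else "sig_lower")
  }
  p <- tryCatch(stats::t.test(l1, l2)$p.value, error = function(e) NA_real_)
  if (is.na(p)) return("ns")
  if (p >= alpha) return("ns")
  if (d > 0) "sig_higher" else "sig_lower"
}

# Mid-parent pseudo-sample: per-replicate-index parental averages. With
# unequal replicate numbers a seed-controlled bootstrap equalizes them.
mpSample <- function(p1, p2, seed = 1L) {
  if (length(p1) != length(p2)) {
    n <- max(length(p1), length(p2))
    set.seed(seed)
    p1 <- sample(p1, n, replace = TRUE)
    p2 <- sample(p2, n, replace = TRUE)
  }
  (p1 + p2) / 2
}

#' Map three significance calls to an inheritance mode
#'
#' Decision table over the F1-vs-high-parent (HP), F1-vs-low-parent (LP)
#' and F1-vs-mid-parent (MP) calls, evaluated with overdominance first:
#' POD (above HP), NOD (below LP), PD (above MP, ns vs HP), ND (below MP,
#' ns vs LP), PPD (above MP, below HP), NPD (below MP, above LP), A (ns
#' vs MP, below HP, above LP), else NC.
#'
#' @param callHP,callLP,callMP calls from [sigCall()] (F1 first).
#' @return one of "POD","NOD","PD","ND","PPD","NPD","A","NC".
#' @export
classifyMode <- function(callHP, callLP, callMP) {
  n <- max(length(callHP), length(callLP), length(callMP))
  callHP <- rep_len(callHP, n); callLP <- rep_len(callLP, n)
  callMP <- rep_len(callMP, n)
  one <- function(hp, lp, mp) {
    if (hp == "sig_higher") return("POD")
    if (lp == "sig_lower") return("NOD")
    if (mp == "sig_higher" && hp == "ns") return("PD")
    if (mp == "sig_lower" && lp == "ns") return("ND")
    if (mp == "sig_higher" && hp == "sig_lower") return("PPD")
    if (mp == "sig_lower" && lp == "sig_higher") return("NPD")
    if (mp == "ns" && hp == "sig_lower" && lp == "sig_higher") return("A")
    "NC"
  }
  vapply(seq_len(n), function(i) one(callHP[i], callLP[i], callMP[i]),
         character(1))
}

#' Classify expression inheritance modes for a gene matrix
#'
#' For each gene: the higher/lower parent is set by the parental means,
#' the mid-parent pseudo-sample is the per-replicate-index parental
#' average, and the three Welch calls feed [classifyMode()]. Genes whose
#' mean TPM is below \code{minMeanTPM} in all three groups are excluded
#' before testing (mode \code{low_expression}).
#'
#' @param tpm numeric matrix, rows = genes; column groups given by
#'   \code{p1Cols}, \code{p2Cols}, \code{f1Cols} (indices or names).
#' @param p1Cols,p2Cols,f1Cols columns of the P1, P2 and F1 replicates.
#' @param alpha significance level (default 0.05).
#' @param minMeanTPM noise floor (default 1).
#' @return a [HeterosisModes-class].
#' @export
classifyExpressionModes <- function(tpm, p1Cols, p2Cols, f1Cols,
                                    alpha = 0.05, minMeanTPM = 1) {
  tpm <- as.matrix(tpm)
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tpm)))
  res <- lapply(seq_len(nrow(tpm)), function(i) {
    p1 <- tpm[i, p1Cols]; p2 <- tpm[i, p2Cols]; f1 <- tpm[i, f1Cols]
    m1 <- mean(p1); m2 <- mean(p2); mf <- mean(f1)
    if (m1 < minMeanTPM && m2 < minMeanTPM && mf < minMeanTPM)
      return(data.frame(gene_id = genes[i], meanP1 = m1, meanP2 = m2,
                        meanF1 = mf, callHP = NA_character_,
                        callLP = NA_character_, callMP = NA_character_,
                        mode = "low_expression", stringsAsFactors = FALSE))
    hp <- if (m1 >= m2) p1 else p2
    lp <- if (m1 >= m2) p2 else p1
    mp <- mpSample(p1, p2)
    cHP <- sigCall(f1, hp, alpha)
    cLP <- sigCall(f1, lp, alpha)
    cMP <- sigCall(f1, mp, alpha)
    data.frame(gene_id = genes[i], meanP1 = m1, meanP2 = m2, meanF1 = mf,
               callHP = cHP, callLP = cLP, callMP = cMP,
               mode = classifyMode(cHP, cLP, cMP), stringsAsFactors = FALSE)
  })
  new("HeterosisModes", calls = do.call(rbind, res), alpha = alpha)
}

#' Retain differentially expressed genes (offspring vs either parent)
#'
#' A gene is retained when it is significantly differentially expressed
#' in at least one of F1-vs-P1 and F1-vs-P2 (Welch test on log2(TPM+1),
#' Benjamini-Hochberg adjusted within each comparison, and |log2 fold
#' change| >= log2(minFold)).
#'
#' @inheritParams classifyExpressionModes
#' @param minFold minimum fold change (default 2).
#' @return logical vector named by gene, TRUE = retained.
#' @export
retainDEGenes <- function(tpm, p1Cols, p2Cols, f1Cols, alpha = 0.05,
                          minFold = 2) {
  tpm <- as.matrix(tpm)
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tpm)))
  testVs <- function(refCols) {
    p <- apply(tpm, 1L, function(x) {
      l1 <- log2(x[f1Cols] + 1); l2 <- log2(x[refCols] + 1)
      if (stats::sd(l1) < 1e-12 && stats::sd(l2) < 1e-12)
        return(if (abs(mean(l1) - mean(l2)) < 1e-12) 1 else 0)
      tryCatch(stats::t.test(l1, l2)$p.value, error = function(e) 1)
    })
    lfc <- apply(tpm, 1L, function(x)
      mean(log2(x[f1Cols] + 1)) - mean(log2(x[refCols] + 1)))
    stats::p.adjust(p, "BH") < alpha & abs(lfc) >= log2(minFold)
  }
  out <- testVs(p1Cols) | testVs(p2Cols)
  names(out) <- genes
  out
}

#' Tabulate inheritance modes and the additive fraction
#'
#' @param x a [HeterosisModes-class] or character vector of modes.
#' @return list with \code{counts} (per mode), \code{nClassified}
#'   (modes other than NC/low_expression), \code{additiveFraction}
#'   (A / classified; NA when nothing classifies), \code{nNC}.
#' @export
tabulateModes <- function(x) {
  modes <- if (is(x, "HeterosisModes")) x@calls$mode else x
  if (!length(modes)) stop("no genes to tabulate", call. = FALSE)
  lev <- c("A", "PD", "ND", "PPD", "NPD", "POD", "NOD", "NC",
           "low_expression")
  counts <- table(factor(modes, levels = lev))
  classified <- sum(counts[c("A", "PD", "ND", "PPD", "NPD", "POD", "NOD")])
  list(counts = counts, nClassified = classified,
       additiveFraction = if (classified > 0)
         unname(counts["A"] / classified) else NA_real_,
       nNC = unname(counts["NC"]))
}
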